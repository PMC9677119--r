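## data_io: readers/writers for peptide lists, predictor score tables and
## proteomes, plus sliding-window fragmentation into k-mers.

#' Construct a PredictorRun
#'
#' Builds a [PredictorRun-class] from vectors. Missing optional fields
#' default to \code{NA}. Peptides are validated against the canonical
#' alphabet; scores are checked against [0, 1]; EL measured scores must
#' be exactly 0 or 1.
#'
#' @param peptide Character vector of peptide sequences.
#' @param predicted_score Numeric scores in [0, 1].
#' @param strong_binder Logical: the predictor's own strong-binder call
#'   (optional).
#' @param measured_score Numeric measured (training/experimental) scores
#'   in [0, 1] (optional).
#' @param assay Character, \code{"BA"} or \code{"EL"} (optional).
#' @param tool,allele Labels for the predictor and allele.
#' @return A [PredictorRun-class] object.
#'
#' @examples
#' PredictorRun(c("AAAAAAAAA", "GGGGGGGGG"), c(0.9, 0.1),
#'              strong_binder = c(TRUE, FALSE))
#' @export
PredictorRun <- function(peptide, predicted_score,
                         strong_binder = NA, measured_score = NA_real_,
                         assay = NA_character_,
                         tool = "predictor", allele = "allele") {
    peptide <- validatePeptides(peptide)
    n <- length(peptide)
    rec <- data.frame(
        peptide = peptide,
        predicted_score = as.numeric(predicted_score),
        strong_binder = as.logical(rep_len(strong_binder, n)),
        measured_score = as.numeric(rep_len(measured_score, n)),
        assay = as.character(rep_len(assay, n)),
        stringsAsFactors = FALSE)
    new("PredictorRun", tool = tool, allele = allele, records = rec)
}

#' Read a peptide list
#'
#' Plain-text format: one peptide sequence per line; blank lines and
#' lines starting with \code{#} are skipped. Sequences are validated
#' against the canonical amino-acid alphabet, and an invalid residue is
#' reported with its line number.
#'
#' @param path Path to the peptide list file.
#' @return Character vector of validated peptides, in file order.
#'
#' @seealso [writePeptideList()]
#' @export
readPeptideList <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    if (!any(keep))
        stop("no peptide sequences found in '", path, "'")
    idx <- which(keep)
    peps <- trimws(lines[keep])
    for (i in seq_along(peps)) {
        ok <- tryCatch({ validatePeptides(peps[i]); TRUE },
                       error = function(e) conditionMessage(e))
        if (!isTRUE(ok))
            stop("line ", idx[i], " of '", path, "': ", ok)
    }
    validatePeptides(peps)
}

#' @rdname readPeptideList
#' @param peptides Character vector of peptides to write.
#' @export
writePeptideList <- function(peptides, path) {
    writeLines(validatePeptides(peptides), path)
    invisible(path)
}

#' Read and write predictor score tables
#'
#' The score-table dialect is a tab-separated file with a header line.
#' Required columns: \code{peptide} and \code{predicted_score} (in
#' [0, 1]). Optional columns: \code{strong_binder} (TRUE/FALSE),
#' \code{measured_score} (in [0, 1]; exactly 0 or 1 when the assay is
#' EL) and \code{assay} (BA or EL). A \code{.} or empty cell marks a
#' missing optional value. \code{writeScoreTable} emits the same dialect
#' with full-precision numbers, so a write/read round trip reproduces
#' every record exactly.
#'
#' @param path Path to the TSV file.
#' @param tool,allele Run labels attached to the returned object (the
#'   file format itself carries no labels).
#' @return \code{readScoreTable} returns a [PredictorRun-class].
#'
#' @export
readScoreTable <- function(path, tool = "predictor", allele = "allele") {
    lines <- readLines(path)
    if (length(lines) < 2L)
        stop("score table '", path, "' has no data rows")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    required <- c("peptide", "predicted_score")
    miss <- setdiff(required, header)
    if (length(miss) > 0)
        stop("score table '", path, "' is missing required column(s): ",
             paste(miss, collapse = ", "))
    cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(cells) != length(header))
    if (length(bad) > 0)
        stop("row ", bad[1L] + 1L, " of '", path, "' has ",
             lengths(cells)[bad[1L]], " fields, expected ", length(header))
    mat <- do.call(rbind, cells)
    colnames(mat) <- header
    getcol <- function(nm) if (nm %in% header) mat[, nm] else NULL
    asMissing <- function(x) ifelse(is.na(x) | x == "." | x == "", NA, x)
    num <- function(x) {
        x <- asMissing(x)
        out <- suppressWarnings(as.numeric(x))
        if (any(!is.na(x) & is.na(out)))
            stop("non-numeric score value in '", path, "'")
        out
    }
    lgl <- function(x) {
        x <- asMissing(x)
        out <- rep(NA, length(x))
        out[!is.na(x) & x %in% c("TRUE", "true", "1")] <- TRUE
        out[!is.na(x) & x %in% c("FALSE", "false", "0")] <- FALSE
        if (any(!is.na(x) & is.na(out)))
            stop("invalid logical value in strong_binder column of '",
                 path, "'")
        out
    }
    ps <- num(mat[, "predicted_score"])
    if (any(is.na(ps)))
        stop("predicted_score is required for every row of '", path, "'")
    if (any(ps < 0 | ps > 1))
        stop("predicted_score outside [0, 1] in '", path, "' (first bad row ",
             which(ps < 0 | ps > 1)[1L] + 1L, ")")
    n <- nrow(mat)
    ms <- if (is.null(getcol("measured_score"))) rep(NA_real_, n)
          else num(getcol("measured_score"))
    if (any(!is.na(ms) & (ms < 0 | ms > 1)))
        stop("measured_score outside [0, 1] in '", path, "'")
    as_ <- if (is.null(getcol("assay"))) rep(NA_character_, n)
           else as.character(asMissing(getcol("assay")))
    el_bad <- !is.na(as_) & as_ == "EL" & !is.na(ms) & !(ms %in% c(0, 1))
    if (any(el_bad))
        stop("EL measured scores must be exactly 0 or 1; violated at row ",
             which(el_bad)[1L] + 1L, " of '", path, "'")
    sb <- if (is.null(getcol("strong_binder"))) rep(NA, n)
          else lgl(getcol("strong_binder"))
    PredictorRun(peptide = mat[, "peptide"], predicted_score = ps,
                 strong_binder = sb, measured_score = ms, assay = as_,
                 tool = tool, allele = allele)
}

#' @rdname readScoreTable
#' @param run A [PredictorRun-class] to serialise.
#' @export
writeScoreTable <- function(run, path) {
    stopifnot(is(run, "PredictorRun"))
    rec <- records(run)
    cell <- function(x, fmt) ifelse(is.na(x), ".", fmt(x))
    lines <- c(
        paste(c("peptide", "predicted_score", "strong_binder",
                "measured_score", "assay"), collapse = "\t"),
        paste(rec$peptide,
              .fmtNum(rec$predicted_score),
              cell(rec$strong_binder, function(x) ifelse(x, "TRUE", "FALSE")),
              cell(rec$measured_score, .fmtNum),
              cell(rec$assay, identity),
              sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read a proteome from FASTA
#'
#' Reads protein sequences with \code{Biostrings::readAAStringSet} and
#' screens them for non-canonical residues (B, J, O, U, X, Z, ...).
#' Under \code{policy = "fail"} any non-canonical residue is an error;
#' under the default \code{policy = "skip-windows"} the proteins are
#' retained and flagged, and [fragmentProteins()] later drops only the
#' k-mer windows that overlap a non-canonical residue.
#'
#' @param path Path to a FASTA file.
#' @param policy \code{"skip-windows"} (default) or \code{"fail"}.
#' @return An \code{AAStringSet}; names are the FASTA headers, and the
#'   metadata column \code{has_noncanonical} flags affected proteins.
#'
#' @export
readFastaProteome <- function(path, policy = c("skip-windows", "fail")) {
    policy <- match.arg(policy)
    prot <- tryCatch(Biostrings::readAAStringSet(path),
                     error = function(e)
                         stop("cannot read FASTA '", path, "': ",
                              conditionMessage(e)))
    if (length(prot) == 0L)
        stop("FASTA '", path, "' contains no sequences")
    seqs <- toupper(as.character(prot))
    flag <- vapply(seqs, function(s)
        any(!(strsplit(s, "")[[1]] %in% .AA_ALPHABET)), logical(1))
    if (policy == "fail" && any(flag))
        stop("non-canonical residue in protein '",
             names(prot)[which(flag)[1L]],
             "' (policy = 'fail'; use 'skip-windows' to keep it)")
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- names(prot)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        has_noncanonical = unname(flag))
    out
}

#' Sample proteins without replacement
#'
#' Uniform random sample of \code{n} proteins, reproducible under a
#' fixed seed.
#'
#' @param proteome An \code{AAStringSet} (or named character vector).
#' @param n Number of proteins to sample (1 <= n <= length).
#' @param seed Optional integer seed.
#' @return The sampled sub-collection, same container as the input.
#'
#' @export
sampleProteins <- function(proteome, n, seed = NULL) {
    size <- length(proteome)
    if (!is.numeric(n) || length(n) != 1L || n < 1L)
        stop("'n' must be a positive count")
    if (n > size)
        stop("cannot sample ", n, " proteins from a proteome of ", size)
    idx <- .withSeed(seed, sample.int(size, as.integer(n)))
    proteome[idx]
}

#' Fragment proteins into k-mers
#'
#' Enumerates every length-\code{k} window at step 1, protein by protein
#' and position by position; window \code{i} covers the 0-based half-open
#' interval \code{[i, i + k)}. Proteins shorter than \code{k} contribute
#' zero windows. Duplicate k-mers are retained by default (set
#' \code{dedup = TRUE} to drop them). Windows containing a non-canonical
#' residue are silently dropped under \code{policy = "skip-windows"} and
#' are an error under \code{policy = "fail"}.
#'
#' @param proteins An \code{AAStringSet} or character vector of protein
#'   sequences.
#' @param k Window length (>= 1); 9 for MHC class I audits.
#' @param dedup Drop duplicate peptides? Default \code{FALSE}.
#' @param policy How to treat non-canonical residues:
#'   \code{"skip-windows"} (default) or \code{"fail"}.
#' @return Character vector of validated k-mer peptides. The total over
#'   proteins of length L_i is \code{sum(max(0, L_i - k + 1))} before
#'   deduplication and window dropping.
#'
#' @examples
#' fragmentProteins("MKTAYIAKQRQ", k = 9)   # 3 windows
#' @export
fragmentProteins <- function(proteins, k = 9,
                             dedup = FALSE,
                             policy = c("skip-windows", "fail")) {
    policy <- match.arg(policy)
    if (is(proteins, "XStringSet"))
        proteins <- as.character(proteins)
    stopifnot(is.character(proteins), is.numeric(k), length(k) == 1L, k >= 1)
    k <- as.integer(k)
    proteins <- toupper(trimws(proteins))
    out <- vector("list", length(proteins))
    for (j in seq_along(proteins)) {
        s <- proteins[j]
        L <- nchar(s)
        if (L < k) {
            out[[j]] <- character(0)
            next
        }
        starts <- seq_len(L - k + 1L)
        wins <- substring(s, starts, starts + k - 1L)
        badpos <- which(!(strsplit(s, "")[[1]] %in% .AA_ALPHABET))
        if (length(badpos) > 0) {
            if (policy == "fail")
                stop("non-canonical residue at position ", badpos[1L],
                     " of protein ", j)
            keep <- !vapply(starts, function(st)
                any(badpos >= st & badpos < st + k), logical(1))
            wins <- wins[keep]
        }
        out[[j]] <- wins
    }
    peps <- unlist(out, use.names = FALSE)
    if (dedup)
        peps <- unique(peps)
    peps
}
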