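## hydro_core: residue-level hydrophobicity scales, peptide totals, and
## the three-way hydrophobicity classification.

## Moon side-chain hydrophobicity scale, in decreasing order. Chosen as
## the default because it targets side-chain hydrophobicity/polarity of
## free residues, which tracks how short peptides behave in aqueous
## solution better than folding-oriented scales.
.MOON_VALUES <- c(
    F =  1.43, L =  1.26, I =  1.15, P =  1.13, Y =  0.94,
    V =  0.80, M =  0.79, W =  0.63, A =  0.46, C =  0.24,
    E = -0.27, G = -0.30, T = -0.33, S = -0.35, D = -0.85,
    Q = -0.88, N = -1.08, R = -1.19, H = -1.65, K = -1.93)

## Registry: known scale names. Only "moon" ships with values; the other
## common hydropathy scales are reserved slots a user can fill via
## registerHydroScale().
.scaleRegistry <- new.env(parent = emptyenv())

.initScaleRegistry <- function() {
    assign("moon",
           new("HydrophobicityScale", name = "moon",
               values = .MOON_VALUES[.AA_ALPHABET]),
           envir = .scaleRegistry)
    for (nm in c("kyte-doolittle", "cornette", "hopp-woods"))
        assign(nm, NULL, envir = .scaleRegistry)
}

#' Retrieve a hydrophobicity scale by name
#'
#' The registry ships the Moon side-chain hydrophobicity scale
#' (\code{"moon"}, the default everywhere in this package). The names
#' \code{"kyte-doolittle"}, \code{"cornette"} and \code{"hopp-woods"} are
#' reserved registry slots without values; use [registerHydroScale()] to
#' supply a custom scale under any name.
#'
#' @param name Scale name; default \code{"moon"}.
#' @return A [HydrophobicityScale-class] object.
#'
#' @examples
#' sc <- hydroScale("moon")
#' scaleValue(sc, "F")   # 1.43, the most hydrophobic residue
#' @export
hydroScale <- function(name = "moon") {
    stopifnot(is.character(name), length(name) == 1L)
    if (!exists(name, envir = .scaleRegistry, inherits = FALSE))
        stop("unknown hydrophobicity scale '", name, "'; known names: ",
             paste(listHydroScales(), collapse = ", "))
    sc <- get(name, envir = .scaleRegistry, inherits = FALSE)
    if (is.null(sc))
        stop("scale '", name, "' is a registry slot without values; ",
             "only 'moon' ships with values. Use registerHydroScale() ",
             "to provide values for it.")
    sc
}

#' @rdname hydroScale
#' @export
listHydroScales <- function() {
    sort(ls(envir = .scaleRegistry))
}

#' @rdname hydroScale
#' @param values Named numeric vector with one value per canonical
#'   amino-acid letter (for \code{registerHydroScale}).
#' @export
registerHydroScale <- function(name, values) {
    sc <- new("HydrophobicityScale", name = name,
              values = values[.AA_ALPHABET])
    validObject(sc)
    assign(name, sc, envir = .scaleRegistry)
    invisible(sc)
}

#' Look up the hydrophobicity of a single residue
#'
#' @param scale A [HydrophobicityScale-class] object.
#' @param residue A single canonical amino-acid letter.
#' @return The stored hydrophobicity value.
#'
#' @examples
#' scaleValue(hydroScale("moon"), "K")  # -1.93, the most hydrophilic
#' @export
scaleValue <- function(scale, residue) {
    stopifnot(is(scale, "HydrophobicityScale"))
    if (!is.character(residue) || length(residue) != 1L ||
        nchar(residue) != 1L)
        stop("'residue' must be a single amino-acid letter")
    if (!(residue %in% .AA_ALPHABET))
        stop("non-canonical residue '", residue, "': the scale covers only ",
             "the 20 canonical amino-acid letters (upper case)")
    unname(scale@values[[residue]])
}

#' Validate and normalise peptide sequences
#'
#' Trims whitespace, upper-cases, and checks every character against the
#' 20-letter canonical amino-acid alphabet. Accepts a character vector or
#' a \code{Biostrings::AAStringSet}.
#'
#' @param peptides Character vector (or \code{AAStringSet}) of peptide
#'   sequences.
#' @return The validated, normalised character vector.
#'
#' @examples
#' validatePeptides(c(" siinfekl ", "GILGFVFTL"))
#' @export
validatePeptides <- function(peptides) {
    if (is(peptides, "XStringSet"))
        peptides <- as.character(peptides)
    if (!is.character(peptides))
        stop("'peptides' must be a character vector or AAStringSet")
    peptides <- toupper(trimws(peptides))
    if (any(!nzchar(peptides)))
        stop("empty peptide sequence at position ",
             which(!nzchar(peptides))[1L])
    letters_used <- unique(strsplit(paste(peptides, collapse = ""), "")[[1]])
    bad <- setdiff(letters_used, .AA_ALPHABET)
    if (length(bad) > 0) {
        offender <- which(vapply(peptides, function(p)
            any(strsplit(p, "")[[1]] %in% bad), logical(1)))[1L]
        stop("non-canonical residue(s) ", paste(bad, collapse = ", "),
             " in peptide ", offender, " ('", peptides[offender], "')")
    }
    peptides
}

## Fast per-peptide sum of per-residue values for equal-length peptides;
## falls back to per-peptide loop for ragged input. Assumes validated
## sequences.
.residueSums <- function(peptides, values) {
    lens <- nchar(peptides)
    if (length(unique(lens)) == 1L) {
        k <- lens[1L]
        tot <- numeric(length(peptides))
        for (i in seq_len(k))
            tot <- tot + values[substr(peptides, i, i)]
        unname(tot)
    } else {
        vapply(strsplit(peptides, ""), function(rs) sum(values[rs]),
               numeric(1))
    }
}

#' Total hydrophobicity of peptides
#'
#' The total hydrophobicity of a peptide is the linear sum of the
#' per-residue scale values — additive in composition and invariant to
#' residue order.
#'
#' @param peptides Character vector (or \code{AAStringSet}) of peptide
#'   sequences; validated and normalised first.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @return Numeric vector of total hydrophobicity values.
#'
#' @examples
#' peptideHydrophobicity(c("AAAAAAAAA", "GGGGGGGGG"))  # 4.14, -2.70
#' @export
peptideHydrophobicity <- function(peptides, scale = hydroScale("moon")) {
    stopifnot(is(scale, "HydrophobicityScale"))
    peptides <- validatePeptides(peptides)
    .residueSums(peptides, scale@values)
}

#' Classify total hydrophobicity into Hydrophobic / Hydrophilic / Balanced
#'
#' Peptides with total hydrophobicity strictly greater than 3 are
#' \code{Hydrophobic}, strictly less than -3 are \code{Hydrophilic}, and
#' everything in between — including the endpoints at exactly +/-3 — is
#' \code{Balanced}. The three classes partition the real line.
#'
#' @param total Numeric vector of total hydrophobicity values (finite).
#' @return Factor with levels \code{Hydrophobic}, \code{Balanced},
#'   \code{Hydrophilic}.
#'
#' @examples
#' classifyHydro(c(4.14, 0, -3))  # Hydrophobic, Balanced, Balanced
#' @export
classifyHydro <- function(total) {
    if (!is.numeric(total) || any(!is.finite(total)))
        stop("'total' must be finite numeric hydrophobicity values")
    cls <- ifelse(total > 3, "Hydrophobic",
                  ifelse(total < -3, "Hydrophilic", "Balanced"))
    factor(cls, levels = c("Hydrophobic", "Balanced", "Hydrophilic"))
}

#' Summarise the hydrophobicity of a peptide set
#'
#' Computes the sample mean and standard deviation (n - 1 denominator) of
#' the total hydrophobicity over a peptide set, and the count of peptides
#' in each hydrophobicity class. A singleton set reports SD 0 with a
#' warning.
#'
#' @inheritParams peptideHydrophobicity
#' @return A list with elements \code{n}, \code{mean}, \code{sd} and
#'   \code{class_counts} (named numeric: Hydrophobic, Balanced,
#'   Hydrophilic).
#'
#' @examples
#' summarizeHydro(c("AAAAAAAAA", "GGGGGGGGG"))$mean  # 0.72
#' @export
summarizeHydro <- function(peptides, scale = hydroScale("moon")) {
    h <- peptideHydrophobicity(peptides, scale)
    if (length(h) == 0L)
        stop("cannot summarise an empty peptide collection")
    s <- if (length(h) == 1L) {
        warning("single peptide: standard deviation reported as 0")
        0
    } else stats::sd(h)
    counts <- table(classifyHydro(h))
    list(n = length(h), mean = mean(h), sd = s,
         class_counts = stats::setNames(as.numeric(counts), names(counts)))
}
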