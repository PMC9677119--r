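## audit_pipeline: end-to-end training-data and proteome audits, and
## report serialisation.

.SCORE_QUANTILE_PROBS <- seq(0, 1, by = 0.01)
.VIOLIN_QUANTILE_PROBS <- seq(0, 1, by = 0.05)

## Quantile table of a score vector (the sorted-score curve in compact
## form: each plot of scores is independently sorted, so quantiles carry
## the same information as the full sorted vector).
.quantileTable <- function(x, probs) {
    data.frame(prob = probs,
               value = unname(stats::quantile(x, probs = probs,
                                              type = 7, names = FALSE)))
}

## Violin data: quantiles plus fixed-width histogram bins of a
## hydrophobicity vector.
.violinData <- function(h, binwidth = 0.5) {
    lo <- floor(min(h) / binwidth) * binwidth
    hi <- ceiling(max(h) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    br <- seq(lo, hi, by = binwidth)
    hs <- graphics::hist(h, breaks = br, plot = FALSE)
    list(quantiles = .quantileTable(h, .VIOLIN_QUANTILE_PROBS),
         histogram = data.frame(mid = hs$mids, count = hs$counts))
}

.hydroSummaryList <- function(h) {
    counts <- table(classifyHydro(h))
    list(n = length(h),
         mean = mean(h),
         sd = if (length(h) > 1) stats::sd(h) else 0,
         class_counts = as.list(stats::setNames(as.numeric(counts),
                                                names(counts))))
}

.asRunList <- function(runs) {
    if (is(runs, "PredictorRun"))
        runs <- list(runs)
    stopifnot(length(runs) >= 1,
              all(vapply(runs, is, logical(1), "PredictorRun")))
    labs <- vapply(runs, toolLabel, character(1))
    if (anyDuplicated(labs))
        stop("run tool labels must be unique: ",
             paste(labs, collapse = ", "))
    names(runs) <- labs
    runs
}

.resolveThreshold <- function(run, thresholds) {
    lab <- toolLabel(run)
    if (is.null(thresholds))
        return(measureThreshold(run))
    if (length(thresholds) == 1L && is.null(names(thresholds)))
        return(as.numeric(thresholds))
    if (!(lab %in% names(thresholds)))
        stop("no threshold supplied for run '", lab, "'")
    as.numeric(thresholds[[lab]])
}

.comparisonList <- function(cmp) {
    list(group_a = cmp$labels[1], group_b = cmp$labels[2],
         n_a = cmp$nA, mean_a = cmp$meanA, sd_a = cmp$sdA,
         n_b = cmp$nB, mean_b = cmp$meanB, sd_b = cmp$sdB,
         t = cmp$t, df = cmp$df, p = cmp$p,
         variant = cmp$variant, note = cmp$note)
}

#' Run the training-data audit
#'
#' For each predictor run (all records must carry measured scores):
#' measures the strong-binder threshold from the run's own flags (or
#' uses a supplied one), labels actual and predicted strong binders,
#' and computes the confusion matrix, hydrophobicity-stratified
#' metrics, ROC/AUC, score-distribution quantiles, and the binder set's
#' hydrophobicity summary and violin data. Across runs it contrasts the
#' binder sets' hydrophobicity with two-sample t-tests, and contrasts
#' BA against EL peptides when assay tags are present.
#'
#' @param runs A [PredictorRun-class] or list of them (unique tool
#'   labels); every record needs a measured score.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @param thresholds Optional fixed thresholds: a single value, or a
#'   named vector/list by tool label. \code{NULL} (default) measures
#'   each run's threshold from its flags.
#' @param variant t-test variant, \code{"welch"} or \code{"pooled"}.
#' @param seed Optional integer recorded in the report metadata (the
#'   audit itself is deterministic).
#' @return An [AuditReport-class] in \code{"training"} mode.
#'
#' @export
runTrainingAudit <- function(runs, scale = hydroScale("moon"),
                             thresholds = NULL,
                             variant = c("welch", "pooled"),
                             seed = NULL) {
    variant <- match.arg(variant)
    runs <- .asRunList(runs)
    for (run in runs)
        if (any(is.na(records(run)$measured_score)))
            stop("run '", toolLabel(run), "': every record must carry a ",
                 "measured score in the training audit")
    runSections <- list()
    taus <- numeric(0)
    log <- character(0)
    for (run in runs) {
        lab <- toolLabel(run)
        tau <- tryCatch(.resolveThreshold(run, thresholds),
                        error = function(e)
                            stop("run '", lab, "': ",
                                 conditionMessage(e), call. = FALSE))
        labels <- binderLabels(run, tau)
        rec <- records(run)
        binderPep <- rec$peptide[labels@predicted]
        h <- peptideHydrophobicity(binderPep, scale)
        cc <- confusionCounts(labels)
        roc <- rocCurve(rec$predicted_score, labels@actual)
        runSections[[lab]] <- list(
            label = lab,
            allele = alleleLabel(run),
            threshold = tau,
            n_records = nrow(rec),
            binder_count = length(binderPep),
            score_quantiles = .quantileTable(rec$predicted_score,
                                             .SCORE_QUANTILE_PROBS),
            binder_hydro = .hydroSummaryList(h),
            violin = .violinData(h),
            confusion = list(tp = cc@tp, fp = cc@fp,
                             tn = cc@tn, fn = cc@fn),
            stratified_metrics = stratifiedMetrics(labels, scale),
            roc = list(auc = aucValue(roc), points = rocPoints(roc)))
        taus[lab] <- tau
        log <- c(log, sprintf(
            "run %s: records=%d threshold=%s binders=%d",
            lab, nrow(rec), format(tau), length(binderPep)))
    }
    comparisons <- list()
    labs <- names(runs)
    if (length(runs) >= 2) {
        for (i in seq_len(length(runs) - 1L))
            for (j in seq(i + 1L, length(runs))) {
                cmp <- compareBinderSets(runs[[i]], runs[[j]],
                                         taus[labs[i]], taus[labs[j]],
                                         scale = scale, variant = variant)
                comparisons[[length(comparisons) + 1L]] <-
                    .comparisonList(cmp)
            }
    }
    baEl <- NULL
    rec1 <- records(runs[[1L]])
    if (any(!is.na(rec1$assay))) {
        nBA <- sum(!is.na(rec1$assay) & rec1$assay == "BA")
        nEL <- sum(!is.na(rec1$assay) & rec1$assay == "EL")
        if (nBA >= 2 && nEL >= 2)
            baEl <- .comparisonList(compareBAEL(rec1, scale = scale,
                                                variant = variant))
    }
    content <- list(
        metadata = list(mode = "training", scale = scaleName(scale),
                        seed = seed, variant = variant,
                        thresholds = as.list(taus)),
        runs = unname(runSections),
        comparisons = comparisons,
        ba_el = baEl,
        log = log)
    new("AuditReport", mode = "training", content = content)
}

#' Run the proteome audit
#'
#' Scores a peptide pool (or a proteome, fragmented into 9-mers first)
#' against fixed strong-binder thresholds. No measured scores exist in
#' this mode, so no confusion matrices or ROC curves are computed: the
#' report carries the pool's and each binder set's hydrophobicity
#' summaries and violin data, score quantiles, binder counts, and
#' cross-run t-tests on binder-set hydrophobicity (skipped, with a
#' note, when a binder set has fewer than 2 peptides).
#'
#' @param pool Character vector of peptides, or an \code{AAStringSet}
#'   proteome to fragment (k = 9).
#' @param runs A [PredictorRun-class] or list of them; records carry
#'   predicted scores for the pool's peptides.
#' @param thresholds Fixed thresholds (single value or named by tool
#'   label); required, since thresholds cannot be measured without
#'   flags in this mode (training-derived thresholds are typically
#'   reused here).
#' @inheritParams runTrainingAudit
#' @return An [AuditReport-class] in \code{"proteome"} mode.
#'
#' @export
runProteomeAudit <- function(pool, runs, thresholds,
                             scale = hydroScale("moon"),
                             variant = c("welch", "pooled"),
                             seed = NULL) {
    variant <- match.arg(variant)
    if (missing(thresholds) || is.null(thresholds))
        stop("proteome audits need fixed thresholds (no measured scores ",
             "exist to derive them from)")
    if (is(pool, "XStringSet")) {
        pool <- fragmentProteins(pool, k = 9)
        if (length(pool) == 0L)
            stop("proteome fragmentation produced no 9-mers: all ",
                 "proteins are shorter than 9 residues")
    }
    pool <- validatePeptides(pool)
    runs <- .asRunList(runs)
    poolH <- peptideHydrophobicity(pool, scale)
    runSections <- list()
    binderH <- list()
    taus <- numeric(0)
    log <- c(sprintf("pool: peptides=%d", length(pool)))
    for (run in runs) {
        lab <- toolLabel(run)
        tau <- .resolveThreshold(run, thresholds)
        rec <- records(run)
        binderPep <- rec$peptide[labelPredictedBinders(run, tau)]
        h <- peptideHydrophobicity(binderPep, scale)
        runSections[[lab]] <- list(
            label = lab,
            allele = alleleLabel(run),
            threshold = tau,
            n_records = nrow(rec),
            binder_count = length(binderPep),
            score_quantiles = .quantileTable(rec$predicted_score,
                                             .SCORE_QUANTILE_PROBS),
            binder_hydro = if (length(h) > 0) .hydroSummaryList(h)
                           else NULL,
            violin = if (length(h) > 0) .violinData(h) else NULL)
        binderH[[lab]] <- h
        taus[lab] <- tau
        log <- c(log, sprintf(
            "run %s: records=%d threshold=%s binders=%d",
            lab, nrow(rec), format(tau), length(binderPep)))
    }
    comparisons <- list()
    skipped <- list()
    labs <- names(runs)
    if (length(runs) >= 2) {
        for (i in seq_len(length(runs) - 1L))
            for (j in seq(i + 1L, length(runs))) {
                ha <- binderH[[labs[i]]]
                hb <- binderH[[labs[j]]]
                if (length(ha) < 2L || length(hb) < 2L) {
                    skipped[[length(skipped) + 1L]] <- list(
                        group_a = labs[i], group_b = labs[j],
                        reason = "a strong-binder set has fewer than 2 peptides")
                    next
                }
                cmp <- twoSampleT(ha, hb, variant = variant,
                                  labels = c(labs[i], labs[j]))
                comparisons[[length(comparisons) + 1L]] <-
                    .comparisonList(cmp)
            }
    }
    content <- list(
        metadata = list(mode = "proteome", scale = scaleName(scale),
                        seed = seed, variant = variant,
                        thresholds = as.list(taus)),
        pool = list(n = length(pool),
                    hydro = .hydroSummaryList(poolH),
                    violin = .violinData(poolH)),
        runs = unname(runSections),
        comparisons = comparisons,
        skipped_comparisons = skipped,
        log = log)
    new("AuditReport", mode = "proteome", content = content)
}

.reportJson <- function(report) {
    jsonlite::toJSON(c(list(mode = report@mode), report@content),
                     auto_unbox = TRUE, digits = NA, na = "null",
                     null = "null", pretty = TRUE)
}

#' Export and re-import an audit report
#'
#' \code{exportReport} writes, into \code{dir}: \code{report.json} (the
#' full report), \code{thresholds.tsv}, \code{comparisons.tsv},
#' \code{violin_data.tsv}, \code{metrics_table.tsv} and one
#' \code{roc_points_<run>.tsv} per run (training mode only), and
#' \code{audit_log.txt} echoing the resolved configuration and
#' per-stage record counts. Output is deterministic: exporting the same
#' report twice yields byte-identical files, and
#' \code{importReport(file.path(dir, "report.json"))} reconstructs a
#' report whose export is byte-identical to the original. Sections a
#' report does not have (e.g. ROC in proteome mode) are omitted, not
#' written empty.
#'
#' @param report An [AuditReport-class] object.
#' @param dir Output directory (created if needed).
#' @return \code{exportReport}: the directory path, invisibly.
#'   \code{importReport}: an [AuditReport-class] object.
#'
#' @export
exportReport <- function(report, dir) {
    stopifnot(is(report, "AuditReport"))
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory '", dir, "'")
    ct <- report@content
    writeLines(.reportJson(report), file.path(dir, "report.json"))
    thr <- do.call(rbind, lapply(ct$runs, function(r)
        data.frame(run = r$label, allele = r$allele,
                   threshold = r$threshold, n_records = r$n_records,
                   binder_count = r$binder_count)))
    .writeTsv(thr, file.path(dir, "thresholds.tsv"))
    if (length(ct$comparisons) > 0) {
        cmp <- do.call(rbind, lapply(ct$comparisons, function(x)
            as.data.frame(x, stringsAsFactors = FALSE)))
        .writeTsv(cmp, file.path(dir, "comparisons.tsv"))
    }
    violin <- do.call(rbind, lapply(ct$runs, function(r) {
        if (is.null(r$violin)) return(NULL)
        rbind(data.frame(run = r$label, part = "quantile",
                         x = r$violin$quantiles$prob,
                         value = r$violin$quantiles$value),
              data.frame(run = r$label, part = "histogram",
                         x = r$violin$histogram$mid,
                         value = r$violin$histogram$count))
    }))
    if (!is.null(ct$pool))
        violin <- rbind(
            data.frame(run = "pool", part = "quantile",
                       x = ct$pool$violin$quantiles$prob,
                       value = ct$pool$violin$quantiles$value),
            data.frame(run = "pool", part = "histogram",
                       x = ct$pool$violin$histogram$mid,
                       value = ct$pool$violin$histogram$count),
            violin)
    if (!is.null(violin))
        .writeTsv(violin, file.path(dir, "violin_data.tsv"))
    if (report@mode == "training") {
        met <- do.call(rbind, lapply(ct$runs, function(r)
            cbind(run = r$label, r$stratified_metrics)))
        .writeTsv(met, file.path(dir, "metrics_table.tsv"))
        for (r in ct$runs)
            .writeTsv(r$roc$points,
                      file.path(dir, paste0("roc_points_",
                                            gsub("[^A-Za-z0-9._-]", "_",
                                                 r$label), ".tsv")))
    }
    md <- ct$metadata
    logLines <- c(
        paste0("mode: ", md$mode),
        paste0("scale: ", md$scale),
        paste0("seed: ", if (is.null(md$seed)) "none" else md$seed),
        paste0("t_test_variant: ", md$variant),
        paste0("thresholds: ",
               paste(names(md$thresholds),
                     vapply(md$thresholds, format, character(1)),
                     sep = "=", collapse = " ")),
        ct$log)
    writeLines(logLines, file.path(dir, "audit_log.txt"))
    invisible(dir)
}

#' @rdname exportReport
#' @param path Path to a \code{report.json} written by
#'   \code{exportReport}.
#' @export
importReport <- function(path) {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    mode <- raw$mode
    raw$mode <- NULL
    ## Table sections are serialised as arrays of row objects; rebuild
    ## them as data.frames.
    rowsToDf <- function(rows) {
        if (is.null(rows) || length(rows) == 0L) return(NULL)
        cols <- names(rows[[1L]])
        out <- lapply(cols, function(nm)
            unlist(lapply(rows, function(r)
                if (is.null(r[[nm]])) NA else r[[nm]]),
                use.names = FALSE))
        names(out) <- cols
        as.data.frame(out, stringsAsFactors = FALSE)
    }
    fixViolin <- function(v) {
        if (is.null(v)) return(NULL)
        list(quantiles = rowsToDf(v$quantiles),
             histogram = rowsToDf(v$histogram))
    }
    raw$runs <- lapply(raw$runs, function(r) {
        r$score_quantiles <- rowsToDf(r$score_quantiles)
        r$violin <- fixViolin(r$violin)
        if (!is.null(r$stratified_metrics))
            r$stratified_metrics <- rowsToDf(r$stratified_metrics)
        if (!is.null(r$roc))
            r$roc$points <- rowsToDf(r$roc$points)
        r
    })
    if (!is.null(raw$pool))
        raw$pool$violin <- fixViolin(raw$pool$violin)
    new("AuditReport", mode = mode, content = raw)
}
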