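## stats_compare: two-sample t-tests on total hydrophobicity, between
## predictors' strong-binder sets and between BA and EL training data.

#' Two-sample t-test on hydrophobicity values
#'
#' Welch's unequal-variance t-test by default (\code{variant =
#' "welch"}), with the classical pooled-variance test available via
#' \code{variant = "pooled"}; p-values are two-sided. When both groups
#' have zero variance the statistic is undefined and an error is raised
#' (distinguishing the equal-mean from the shifted case in the
#' message). The result carries a significance note that renders small
#' p-values in the conventional bound form (\code{"p < 0.0001"}).
#'
#' @param groupA,groupB Numeric vectors (n >= 2 each).
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @param labels Character vector of two group labels for the report.
#' @return A list of class \code{hydroComparison}: per-group \code{n},
#'   \code{mean}, \code{sd}; \code{t}; \code{df}; \code{p} (two-sided);
#'   \code{variant}; \code{note}.
#'
#' @examples
#' twoSampleT(rnorm(50), rnorm(50) + 1)
#' @export
twoSampleT <- function(groupA, groupB, variant = c("welch", "pooled"),
                       labels = c("A", "B")) {
    variant <- match.arg(variant)
    a <- as.numeric(groupA)
    b <- as.numeric(groupB)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values (got ", length(a),
             " and ", length(b), ")")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("non-finite values in input groups")
    va <- stats::var(a)
    vb <- stats::var(b)
    if (va == 0 && vb == 0) {
        if (mean(a) == mean(b))
            stop("both groups are constant with equal means: ",
                 "t statistic undefined (0/0)")
        stop("both groups are constant: t statistic is unbounded; ",
             "add measurement jitter or use more data")
    }
    tt <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                        alternative = "two.sided")
    p <- unname(tt$p.value)
    note <- if (p < 1e-4) "p < 0.0001"
            else if (p < 0.05) sprintf("significant (p = %.4g)", p)
            else sprintf("not significant (p = %.4g)", p)
    structure(list(
        labels = labels,
        nA = length(a), meanA = mean(a), sdA = stats::sd(a),
        nB = length(b), meanB = mean(b), sdB = stats::sd(b),
        t = unname(tt$statistic), df = unname(tt$parameter), p = p,
        variant = variant, note = note), class = "hydroComparison")
}

#' @export
print.hydroComparison <- function(x, ...) {
    cat("Two-sample t-test (", x$variant, "), two-sided\n", sep = "")
    cat(sprintf("  %s: n = %d, mean = %.4g, sd = %.4g\n",
                x$labels[1], x$nA, x$meanA, x$sdA))
    cat(sprintf("  %s: n = %d, mean = %.4g, sd = %.4g\n",
                x$labels[2], x$nB, x$meanB, x$sdB))
    cat(sprintf("  t = %.4g, df = %.4g, p = %.4g (%s)\n",
                x$t, x$df, x$p, x$note))
    if (!is.null(x$class_counts)) {
        cat("  hydrophobicity classes:\n")
        for (nm in names(x$class_counts))
            cat("    ", nm, ": ",
                paste(names(x$class_counts[[nm]]),
                      x$class_counts[[nm]], sep = "=", collapse = " "),
                "\n", sep = "")
    }
    invisible(x)
}

#' Compare two predictors' strong-binder sets by hydrophobicity
#'
#' Labels each run's predicted strong binders with its own threshold,
#' computes the total hydrophobicity of each binder set, and contrasts
#' the two sets with [twoSampleT()]. Also reports each set's size and
#' hydrophobicity-class composition.
#'
#' @param runA,runB [PredictorRun-class] objects.
#' @param thresholdA,thresholdB Score thresholds; \code{NULL} measures
#'   each from the run's own flags.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @inheritParams twoSampleT
#' @return A \code{hydroComparison} list with added \code{class_counts}.
#'
#' @export
compareBinderSets <- function(runA, runB, thresholdA = NULL,
                              thresholdB = NULL,
                              scale = hydroScale("moon"),
                              variant = c("welch", "pooled")) {
    stopifnot(is(runA, "PredictorRun"), is(runB, "PredictorRun"))
    if (is.null(thresholdA)) thresholdA <- measureThreshold(runA)
    if (is.null(thresholdB)) thresholdB <- measureThreshold(runB)
    binders <- function(run, thr) {
        rec <- records(run)
        rec$peptide[labelPredictedBinders(run, thr)]
    }
    pa <- binders(runA, thresholdA)
    pb <- binders(runB, thresholdB)
    if (length(pa) < 2L || length(pb) < 2L)
        stop("each run's strong-binder set needs at least 2 peptides ",
             "(got ", length(pa), " and ", length(pb), ")")
    ha <- peptideHydrophobicity(pa, scale)
    hb <- peptideHydrophobicity(pb, scale)
    out <- twoSampleT(ha, hb, variant = variant,
                      labels = c(toolLabel(runA), toolLabel(runB)))
    out$class_counts <- list(
        stats::setNames(as.numeric(table(classifyHydro(ha))),
                        levels(classifyHydro(0))),
        stats::setNames(as.numeric(table(classifyHydro(hb))),
                        levels(classifyHydro(0))))
    names(out$class_counts) <- out$labels
    out
}

#' Compare BA and EL training data by hydrophobicity
#'
#' Splits training-style records by assay tag and contrasts the total
#' hydrophobicity of the binding-affinity (BA) peptides against the
#' eluted-ligand (EL) peptides with [twoSampleT()]. Group A is BA, so a
#' positive mean difference means the BA data are the more hydrophobic
#' set.
#'
#' @param records A [PredictorRun-class] or a \code{data.frame} with
#'   columns \code{peptide} and \code{assay}.
#' @inheritParams compareBinderSets
#' @return A \code{hydroComparison} list, labels \code{c("BA", "EL")}.
#'
#' @export
compareBAEL <- function(records, scale = hydroScale("moon"),
                        variant = c("welch", "pooled")) {
    rec <- if (is(records, "PredictorRun")) records(records) else records
    if (!all(c("peptide", "assay") %in% names(rec)))
        stop("records need 'peptide' and 'assay' columns")
    if (all(is.na(rec$assay)))
        stop("no assay tags present; BA vs EL comparison impossible")
    ba <- rec$peptide[!is.na(rec$assay) & rec$assay == "BA"]
    el <- rec$peptide[!is.na(rec$assay) & rec$assay == "EL"]
    if (length(ba) < 2L || length(el) < 2L)
        stop("both BA and EL groups need at least 2 records ",
             "(got ", length(ba), " BA and ", length(el), " EL)")
    twoSampleT(peptideHydrophobicity(ba, scale),
               peptideHydrophobicity(el, scale),
               variant = variant, labels = c("BA", "EL"))
}
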