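## metrics: confusion matrices, accuracy/precision/recall/F1, ROC/AUC,
## and the hydrophobicity-stratified metrics table.

#' Confusion counts from binder labels
#'
#' Standard 2x2 counts with strong binders as the positive class.
#' Records whose actual label is \code{NA} (no measured score) are
#' excluded before counting.
#'
#' @param labels A [BinderLabels-class] object (or a list/data.frame
#'   with logical elements \code{actual} and \code{predicted}).
#' @return A [ConfusionCounts-class] object.
#'
#' @export
confusionCounts <- function(labels) {
    if (is(labels, "BinderLabels")) {
        actual <- labels@actual
        predicted <- labels@predicted
    } else {
        actual <- labels$actual
        predicted <- labels$predicted
    }
    keep <- !is.na(actual)
    actual <- actual[keep]
    predicted <- predicted[keep]
    if (length(actual) == 0L)
        stop("no records with both actual and predicted labels")
    new("ConfusionCounts",
        tp = sum(actual & predicted),
        fp = sum(!actual & predicted),
        tn = sum(!actual & !predicted),
        fn = sum(actual & !predicted))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / N, precision = TP / (TP + FP), recall =
#' TP / (TP + FN), and F1 the harmonic mean of precision and recall.
#' A zero denominator yields \code{NA} (the undefined marker) rather
#' than an error or a division by zero; all-zero counts are an error.
#'
#' @param cc A [ConfusionCounts-class] object.
#' @return One-row \code{data.frame} with columns \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}.
#'
#' @examples
#' computeMetrics(new("ConfusionCounts", tp = 1L, fp = 1L,
#'                    tn = 1L, fn = 1L))  # all four metrics 0.5
#' @export
computeMetrics <- function(cc) {
    stopifnot(is(cc, "ConfusionCounts"))
    tp <- cc@tp; fp <- cc@fp; tn <- cc@tn; fn <- cc@fn
    n <- tp + fp + tn + fn
    if (n == 0L)
        stop("all confusion counts are zero; no records to score")
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    precision <- safe(tp, tp + fp)
    recall <- safe(tp, tp + fn)
    f1 <- if (is.na(precision) || is.na(recall)) NA_real_
          else if (precision + recall == 0) NA_real_
          else 2 * precision * recall / (precision + recall)
    data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
               accuracy = (tp + tn) / n,
               precision = precision, recall = recall, f1 = f1)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct predicted scores in
#' descending order, grouping tied scores into single steps, and anchors
#' the curve at (0, 0) and (1, 1). The area under the curve is computed
#' by the trapezoidal rule, which with this tie handling equals the
#' Mann-Whitney concordance probability: the chance that a random actual
#' positive outscores a random actual negative, ties counting one half.
#'
#' @param scores Numeric predicted scores.
#' @param actual Logical actual labels (\code{NA} entries are dropped);
#'   both classes must be present.
#' @return A [ROCCurve-class] object. The (0, 0) anchor carries an
#'   \code{NA} threshold (no finite threshold reaches it).
#'
#' @examples
#' roc <- rocCurve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
#' aucValue(roc)  # 0.75
#' @export
rocCurve <- function(scores, actual) {
    keep <- !is.na(actual) & !is.na(scores)
    scores <- scores[keep]
    actual <- as.logical(actual[keep])
    nP <- sum(actual)
    nN <- sum(!actual)
    if (nP == 0L || nN == 0L)
        stop("ROC requires at least one actual positive and one actual ",
             "negative; got ", nP, " positives and ", nN, " negatives")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    a <- actual[ord]
    ## one step per distinct score: cumulative counts at the last
    ## occurrence of each tied block
    ends <- c(which(diff(s) != 0), length(s))
    posAt <- cumsum(a)[ends]
    negAt <- cumsum(!a)[ends]
    pts <- data.frame(threshold = c(NA_real_, s[ends]),
                      fpr = c(0, negAt / nN),
                      tpr = c(0, posAt / nP))
    auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                    utils::tail(pts$tpr, -1)) / 2)
    new("ROCCurve", points = pts, auc = auc)
}

#' Hydrophobicity-stratified metrics table
#'
#' Computes confusion counts and the four classification metrics
#' overall and separately for the Hydrophobic, Hydrophilic and Balanced
#' peptide classes (each record belongs to exactly one class by
#' [classifyHydro()]), mirroring the per-class breakdown used to locate
#' hydrophobic false positives and hydrophilic false negatives. The
#' per-class confusion counts sum component-wise to the All row. A
#' class with no records gets zero counts and \code{NA} metrics.
#'
#' @param labels A [BinderLabels-class] object.
#' @param scale A [HydrophobicityScale-class]; default Moon.
#' @return \code{data.frame} with a \code{peptide_case} column
#'   (\code{All}, \code{Hydrophobic only}, \code{Hydrophilic only},
#'   \code{Balanced only}) plus the [computeMetrics()] columns.
#'
#' @export
stratifiedMetrics <- function(labels, scale = hydroScale("moon")) {
    stopifnot(is(labels, "BinderLabels"))
    keep <- !is.na(labels@actual)
    if (!any(keep))
        stop("no records with actual labels; nothing to stratify")
    pep <- labels@peptide[keep]
    actual <- labels@actual[keep]
    predicted <- labels@predicted[keep]
    cls <- classifyHydro(peptideHydrophobicity(pep, scale))
    caseOf <- list("All" = rep(TRUE, length(pep)),
                   "Hydrophobic only" = cls == "Hydrophobic",
                   "Hydrophilic only" = cls == "Hydrophilic",
                   "Balanced only" = cls == "Balanced")
    rows <- lapply(names(caseOf), function(nm) {
        sel <- caseOf[[nm]]
        row <- if (!any(sel)) {
            data.frame(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                       accuracy = NA_real_, precision = NA_real_,
                       recall = NA_real_, f1 = NA_real_)
        } else {
            computeMetrics(confusionCounts(
                list(actual = actual[sel], predicted = predicted[sel])))
        }
        cbind(peptide_case = nm, row)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
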