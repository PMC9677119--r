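## thresholding: empirical strong-binder thresholds and binder labelling.

#' Measure a predictor's strong-binder threshold
#'
#' A predictor that flags its own strong binders implicitly defines a
#' score threshold: the lowest predicted score among the records it
#' flagged. Every flagged record then scores at or above the threshold,
#' so re-labelling with it never loses a flagged binder.
#'
#' @param run A [PredictorRun-class] with at least one
#'   \code{strong_binder = TRUE} record.
#' @return The threshold tau, a score in [0, 1].
#'
#' @examples
#' run <- PredictorRun(c("AAAAAAAAA", "AAAAAAAAK", "AAAAAAAKK"),
#'                     c(0.70, 0.551, 0.90),
#'                     strong_binder = c(TRUE, TRUE, TRUE))
#' measureThreshold(run)  # 0.551
#' @export
measureThreshold <- function(run) {
    stopifnot(is(run, "PredictorRun"))
    rec <- records(run)
    flagged <- !is.na(rec$strong_binder) & rec$strong_binder
    if (!any(flagged))
        stop("run '", toolLabel(run), "' has no flagged strong binders; ",
             "supply a fixed threshold instead (threshold = <value>)")
    min(rec$predicted_score[flagged])
}

#' Label actual strong binders
#'
#' Applies a threshold to the measured (training/experimental) scores:
#' a record is an actual strong binder when its measured score is at or
#' above tau. Scores exactly equal to tau are positive — tau is itself
#' attained by a flagged strong binder, so the attaining record must
#' stay positive; the same convention is applied to measured scores for
#' symmetry. Records without a measured score get \code{NA}.
#'
#' @param run A [PredictorRun-class] whose records carry measured
#'   scores.
#' @param threshold The score threshold tau in [0, 1].
#' @return Logical vector, one element per record (\code{NA} where no
#'   measured score exists).
#'
#' @seealso [binderLabels()] for the combined actual/predicted labelling.
#' @export
labelActualBinders <- function(run, threshold) {
    stopifnot(is(run, "PredictorRun"))
    .checkThreshold(threshold)
    ms <- records(run)$measured_score
    if (all(is.na(ms)))
        stop("no record in run '", toolLabel(run),
             "' has a measured score; actual binders cannot be labelled")
    ms >= threshold
}

#' Label predicted strong binders
#'
#' A record is a predicted strong binder when its predicted score is at
#' or above tau (ties at tau are positive). With tau from
#' [measureThreshold()], every record the predictor flagged is
#' predicted-positive.
#'
#' @inheritParams labelActualBinders
#' @return Logical vector, one element per record.
#'
#' @export
labelPredictedBinders <- function(run, threshold) {
    stopifnot(is(run, "PredictorRun"))
    .checkThreshold(threshold)
    records(run)$predicted_score >= threshold
}

.checkThreshold <- function(threshold) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        !is.finite(threshold) || threshold < 0 || threshold > 1)
        stop("'threshold' must be a single score in [0, 1]")
}

#' Label a run's records on both sides
#'
#' Convenience wrapper combining [labelActualBinders()] and
#' [labelPredictedBinders()] into a [BinderLabels-class] object. If no
#' threshold is given it is measured from the run's own strong-binder
#' flags. Records without a measured score receive \code{NA} actual
#' labels and are counted in \code{nUnmeasured}.
#'
#' @inheritParams labelActualBinders
#' @param threshold Threshold tau; \code{NULL} (default) measures it
#'   from the run via [measureThreshold()].
#' @param requireMeasured Error when no record has a measured score?
#'   Default \code{TRUE}; set \code{FALSE} for proteome-mode runs.
#' @return A [BinderLabels-class] object.
#'
#' @export
binderLabels <- function(run, threshold = NULL, requireMeasured = TRUE) {
    stopifnot(is(run, "PredictorRun"))
    if (is.null(threshold))
        threshold <- measureThreshold(run)
    .checkThreshold(threshold)
    rec <- records(run)
    actual <- if (requireMeasured) labelActualBinders(run, threshold)
              else rec$measured_score >= threshold
    new("BinderLabels",
        peptide = rec$peptide,
        actual = actual,
        predicted = labelPredictedBinders(run, threshold),
        threshold = threshold,
        nUnmeasured = sum(is.na(rec$measured_score)))
}
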