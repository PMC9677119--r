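#' @import methods
NULL

## Canonical amino-acid alphabet, in the conventional one-letter order.
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' HydrophobicityScale class
#'
#' A per-residue side-chain hydrophobicity scale: one dimensionless value
#' for each of the 20 canonical amino acids. Peptide hydrophobicity is the
#' linear sum of per-residue values, so a scale fully determines the
#' peptide-level score.
#'
#' @slot name Scale identifier (e.g. \code{"moon"}).
#' @slot values Named numeric vector with exactly one entry per canonical
#'   amino-acid letter.
#'
#' @seealso [hydroScale()], [peptideHydrophobicity()]
#' @exportClass HydrophobicityScale
setClass("HydrophobicityScale",
         representation(name = "character", values = "numeric"))

setValidity("HydrophobicityScale", function(object) {
    v <- object@values
    if (length(object@name) != 1L || !nzchar(object@name))
        return("'name' must be a single non-empty string")
    if (length(v) != 20L)
        return(sprintf("scale must have exactly 20 values, got %d", length(v)))
    if (!setequal(names(v), .AA_ALPHABET))
        return("scale values must be named by the 20 canonical amino-acid letters")
    if (any(!is.finite(v)))
        return("scale values must all be finite")
    TRUE
})

#' PredictorRun class
#'
#' One predictor's scores on one peptide set for one MHC allele: the unit
#' consumed by thresholding, metrics and the audit pipeline. Records carry
#' the predicted binding score in [0, 1], optionally the predictor's own
#' strong-binder call, and optionally a measured (training/experimental)
#' score with its assay tag (\code{"BA"} for continuous binding-affinity
#' data, \code{"EL"} for binary eluted-ligand data).
#'
#' @slot tool Label of the predictor that produced the scores.
#' @slot allele MHC allele label (e.g. \code{"HLA-A*02:01"}).
#' @slot records \code{data.frame} with columns \code{peptide},
#'   \code{predicted_score}, \code{strong_binder} (logical, may be NA),
#'   \code{measured_score} (may be NA) and \code{assay} (may be NA).
#'
#' @seealso [PredictorRun()], [readScoreTable()], [measureThreshold()]
#' @exportClass PredictorRun
setClass("PredictorRun",
         representation(tool = "character", allele = "character",
                        records = "data.frame"))

.REQUIRED_RECORD_COLS <- c("peptide", "predicted_score", "strong_binder",
                           "measured_score", "assay")

setValidity("PredictorRun", function(object) {
    rec <- object@records
    if (length(object@tool) != 1L || length(object@allele) != 1L)
        return("'tool' and 'allele' must be single strings")
    if (!all(.REQUIRED_RECORD_COLS %in% names(rec)))
        return(sprintf("records must have columns: %s",
                       paste(.REQUIRED_RECORD_COLS, collapse = ", ")))
    if (nrow(rec) == 0L)
        return("a PredictorRun must contain at least one record")
    ps <- rec$predicted_score
    if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
        return("predicted_score values must all lie in [0, 1]")
    ms <- rec$measured_score
    bad <- !is.na(ms) & (ms < 0 | ms > 1)
    if (any(bad))
        return("measured_score values must lie in [0, 1] where present")
    as <- rec$assay
    if (any(!is.na(as) & !(as %in% c("BA", "EL"))))
        return("assay must be 'BA' or 'EL' where present")
    el <- !is.na(as) & as == "EL" & !is.na(ms)
    if (any(el & !(ms %in% c(0, 1))))
        return("EL measured scores must be exactly 0 or 1")
    TRUE
})

#' BinderLabels class
#'
#' Actual and predicted strong-binder calls for the records of a
#' [PredictorRun()], together with the score threshold used to make them.
#' Actual labels are \code{NA} for records that carry no measured score
#' (proteome-mode records); such records are excluded from confusion
#' counts and reported via \code{nUnmeasured}.
#'
#' @slot peptide Peptide sequences, one per record.
#' @slot actual Logical: measured score at or above the threshold
#'   (\code{NA} where no measured score exists).
#' @slot predicted Logical: predicted score at or above the threshold.
#' @slot threshold The score threshold tau applied to both sides.
#' @slot nUnmeasured Number of records lacking a measured score.
#'
#' @seealso [binderLabels()], [confusionCounts()]
#' @exportClass BinderLabels
setClass("BinderLabels",
         representation(peptide = "character", actual = "logical",
                        predicted = "logical", threshold = "numeric",
                        nUnmeasured = "integer"))

setValidity("BinderLabels", function(object) {
    n <- length(object@peptide)
    if (length(object@actual) != n || length(object@predicted) != n)
        return("'actual' and 'predicted' must match the number of peptides")
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        return("'threshold' must be a single finite value")
    if (any(is.na(object@predicted)))
        return("'predicted' labels cannot be NA")
    TRUE
})

#' ConfusionCounts class
#'
#' The 2x2 confusion matrix of a strong-binder classification: positives
#' are strong binders.
#'
#' @slot tp,fp,tn,fn Non-negative integer counts.
#'
#' @seealso [confusionCounts()], [computeMetrics()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
         representation(tp = "integer", fp = "integer",
                        tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
        return("tp, fp, tn, fn must be single non-negative integers")
    TRUE
})

#' ROCCurve class
#'
#' A receiver operating characteristic curve built by sweeping the
#' threshold over the distinct predicted scores in descending order, with
#' tied scores grouped so that the trapezoidal area under the curve equals
#' the Mann-Whitney concordance probability (ties counting one half).
#'
#' @slot points \code{data.frame} with columns \code{threshold},
#'   \code{fpr}, \code{tpr}; anchored at (0, 0) and (1, 1).
#' @slot auc Trapezoidal area under the curve, in [0, 1].
#'
#' @seealso [rocCurve()], [aucValue()]
#' @exportClass ROCCurve
setClass("ROCCurve",
         representation(points = "data.frame", auc = "numeric"))

setValidity("ROCCurve", function(object) {
    p <- object@points
    if (!all(c("threshold", "fpr", "tpr") %in% names(p)))
        return("points must have columns threshold, fpr, tpr")
    if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
        return("fpr and tpr must be monotone non-decreasing")
    if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
        return("auc must be a single value in [0, 1]")
    TRUE
})

#' MotifModel class
#'
#' A stylised anchor-residue binding model for one MHC allele. Each anchor
#' position carries a set of favoured residues and a reward weight; a
#' peptide scores \code{baseline + sum(reward or -penalty per anchor)} and
#' the latent binding probability is the logistic transform of
#' \code{steepness} times that raw score.
#'
#' @slot allele Allele label.
#' @slot anchors Named list: 1-based position (as name) to character vector
#'   of favoured residues.
#' @slot reward Numeric reward per matched anchor (recycled across
#'   anchors).
#' @slot penalty Numeric penalty per mismatched anchor (non-negative,
#'   recycled).
#' @slot baseline Baseline raw score (offset before the logistic).
#' @slot steepness Positive logistic steepness.
#'
#' @seealso [motifPreset()], [trueBindingScore()]
#' @exportClass MotifModel
setClass("MotifModel",
         representation(allele = "character", anchors = "list",
                        reward = "numeric", penalty = "numeric",
                        baseline = "numeric", steepness = "numeric"))

setValidity("MotifModel", function(object) {
    a <- object@anchors
    if (length(a) == 0L)
        return("at least one anchor position is required")
    pos <- suppressWarnings(as.integer(names(a)))
    if (any(is.na(pos)) || any(pos < 1L))
        return("anchor names must be positive integer positions")
    if (!all(vapply(a, function(x) is.character(x) && length(x) > 0 &&
                        all(x %in% .AA_ALPHABET), logical(1))))
        return("each anchor must be a non-empty set of canonical residues")
    k <- length(a)
    if (!(length(object@reward) %in% c(1L, k)) ||
        !(length(object@penalty) %in% c(1L, k)))
        return("reward and penalty must have length 1 or one per anchor")
    if (any(!is.finite(object@reward)) || any(!is.finite(object@penalty)) ||
        any(object@penalty < 0))
        return("reward must be finite; penalty finite and non-negative")
    if (length(object@steepness) != 1L || !is.finite(object@steepness) ||
        object@steepness <= 0)
        return("steepness must be a single positive value")
    if (length(object@baseline) != 1L || !is.finite(object@baseline))
        return("baseline must be a single finite value")
    TRUE
})

#' BiasedPredictor class
#'
#' A synthetic predictor defined relative to the latent true binding
#' score: on the logit scale it adds Gaussian noise and a hydrophobicity
#' bias of \code{beta} per unit of total peptide hydrophobicity.
#' \code{beta = 0} is the unbiased predictor.
#'
#' @slot label Predictor label used in reports.
#' @slot noiseSd Standard deviation of the additive logit-scale noise
#'   (non-negative).
#' @slot beta Hydrophobicity bias coefficient per hydrophobicity unit on
#'   the logit scale.
#'
#' @seealso [BiasedPredictor()], [genPredictorScores()]
#' @exportClass BiasedPredictor
setClass("BiasedPredictor",
         representation(label = "character", noiseSd = "numeric",
                        beta = "numeric"))

setValidity("BiasedPredictor", function(object) {
    if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
        object@noiseSd < 0)
        return("noiseSd must be a single non-negative value")
    if (length(object@beta) != 1L || !is.finite(object@beta))
        return("beta must be a single finite value")
    TRUE
})

#' TrainingSetSpec class
#'
#' Parameters of the synthetic training-score generator: how many records,
#' what fraction of peptides are binders, what fraction of records carry a
#' measured score strictly inside (0, 1) rather than exactly 0 or 1, and
#' what fraction of records come from continuous binding-affinity (BA)
#' assays rather than binary eluted-ligand (EL) assays. Only BA records
#' can be non-extreme, so the non-extreme fraction cannot exceed the BA
#' fraction.
#'
#' @slot n Number of records.
#' @slot binderFraction Target fraction of true binders.
#' @slot nonExtremeFraction Fraction of all records with a measured score
#'   strictly in (0, 1); default 0.15.
#' @slot baFraction Fraction of records from BA assays; default 0.2.
#'
#' @seealso [TrainingSetSpec()], [genTrainingSet()]
#' @exportClass TrainingSetSpec
setClass("TrainingSetSpec",
         representation(n = "integer", binderFraction = "numeric",
                        nonExtremeFraction = "numeric",
                        baFraction = "numeric"))

setValidity("TrainingSetSpec", function(object) {
    if (object@n < 1L)
        return("n must be at least 1")
    fr <- c(object@binderFraction, object@nonExtremeFraction,
            object@baFraction)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
        return("all fractions must lie in [0, 1]")
    if (object@nonExtremeFraction > object@baFraction)
        return("nonExtremeFraction cannot exceed baFraction: only BA records can have non-extreme scores")
    TRUE
})

#' AuditReport class
#'
#' The full result of a training-data or proteome audit: thresholds,
#' score-distribution quantiles, per-run binder-set hydrophobicity
#' summaries and violin data, stratified classification metrics and
#' ROC/AUC (training mode only), and cross-run comparison tests.
#' Proteome-mode reports carry no confusion-matrix or ROC sections
#' because no measured scores exist in that mode.
#'
#' @slot mode Either \code{"training"} or \code{"proteome"}.
#' @slot content Nested list with the report sections; see
#'   [reportContent()].
#'
#' @seealso [runTrainingAudit()], [runProteomeAudit()], [exportReport()]
#' @exportClass AuditReport
setClass("AuditReport",
         representation(mode = "character", content = "list"))

setValidity("AuditReport", function(object) {
    if (!(object@mode %in% c("training", "proteome")))
        return("mode must be 'training' or 'proteome'")
    if (object@mode == "proteome") {
        for (run in object@content$runs)
            if (!is.null(run$confusion) || !is.null(run$roc) ||
                !is.null(run$stratified_metrics))
                return("proteome-mode reports cannot contain confusion/ROC sections")
    }
    TRUE
})
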