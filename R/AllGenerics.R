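#' Accessors for hydroMHC classes
#'
#' Small accessor generics so that slot access never appears in user code:
#' \code{scaleName}/\code{scaleValues} for [HydrophobicityScale-class]
#' objects, \code{toolLabel}/\code{alleleLabel}/\code{records} for
#' [PredictorRun-class] objects, \code{thresholdUsed} for
#' [BinderLabels-class], \code{rocPoints}/\code{aucValue} for
#' [ROCCurve-class], and \code{reportMode}/\code{reportContent} for
#' [AuditReport-class].
#'
#' @param x An object of the relevant class.
#' @return The slot value.
#' @name accessors
#' @aliases scaleName scaleValues toolLabel alleleLabel records
#'   thresholdUsed rocPoints aucValue reportMode reportContent
#'
#' @examples
#' scaleValues(hydroScale("moon"))[["F"]]
NULL

#' @rdname accessors
#' @export
setGeneric("scaleName", function(x) standardGeneric("scaleName"))
#' @rdname accessors
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))
#' @rdname accessors
#' @export
setGeneric("toolLabel", function(x) standardGeneric("toolLabel"))
#' @rdname accessors
#' @export
setGeneric("alleleLabel", function(x) standardGeneric("alleleLabel"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("reportMode", function(x) standardGeneric("reportMode"))
#' @rdname accessors
#' @export
setGeneric("reportContent", function(x) standardGeneric("reportContent"))

setMethod("scaleName", "HydrophobicityScale", function(x) x@name)
setMethod("scaleValues", "HydrophobicityScale", function(x) x@values)
setMethod("toolLabel", "PredictorRun", function(x) x@tool)
setMethod("alleleLabel", "PredictorRun", function(x) x@allele)
setMethod("records", "PredictorRun", function(x) x@records)
setMethod("thresholdUsed", "BinderLabels", function(x) x@threshold)
setMethod("rocPoints", "ROCCurve", function(x) x@points)
setMethod("aucValue", "ROCCurve", function(x) x@auc)
setMethod("reportMode", "AuditReport", function(x) x@mode)
setMethod("reportContent", "AuditReport", function(x) x@content)

setMethod("show", "HydrophobicityScale", function(object) {
    cat("HydrophobicityScale '", object@name, "' (20 residues)\n", sep = "")
    v <- sort(object@values, decreasing = TRUE)
    cat("  ", paste(sprintf("%s=%.2f", names(v), v), collapse = " "), "\n",
        sep = "")
})

setMethod("show", "PredictorRun", function(object) {
    rec <- object@records
    cat("PredictorRun: ", object@tool, " on ", object@allele, "\n", sep = "")
    cat("  records: ", nrow(rec),
        "; flagged strong binders: ", sum(rec$strong_binder, na.rm = TRUE),
        "; with measured score: ", sum(!is.na(rec$measured_score)), "\n",
        sep = "")
})

setMethod("show", "BinderLabels", function(object) {
    cat("BinderLabels (threshold = ", format(object@threshold), ")\n",
        sep = "")
    cat("  records: ", length(object@peptide),
        "; predicted positive: ", sum(object@predicted),
        "; actual positive: ", sum(object@actual, na.rm = TRUE),
        "; unmeasured: ", object@nUnmeasured, "\n", sep = "")
})

setMethod("show", "ConfusionCounts", function(object) {
    cat("ConfusionCounts: TP=", object@tp, " FP=", object@fp,
        " TN=", object@tn, " FN=", object@fn, "\n", sep = "")
})

setMethod("show", "ROCCurve", function(object) {
    cat("ROCCurve: ", nrow(object@points), " points, AUC = ",
        format(object@auc, digits = 4), "\n", sep = "")
})

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel for ", object@allele, "\n", sep = "")
    for (i in seq_along(object@anchors))
        cat("  position ", names(object@anchors)[i], ": {",
            paste(object@anchors[[i]], collapse = ","), "}\n", sep = "")
    cat("  baseline = ", object@baseline, ", steepness = ",
        object@steepness, "\n", sep = "")
})

setMethod("show", "BiasedPredictor", function(object) {
    cat("BiasedPredictor '", object@label, "': beta = ", object@beta,
        ", noiseSd = ", object@noiseSd,
        if (object@beta == 0) " (unbiased)" else "", "\n", sep = "")
})

setMethod("show", "TrainingSetSpec", function(object) {
    cat("TrainingSetSpec: n = ", object@n,
        ", binder fraction = ", object@binderFraction,
        ", non-extreme fraction = ", object@nonExtremeFraction,
        ", BA fraction = ", object@baFraction, "\n", sep = "")
})

setMethod("show", "AuditReport", function(object) {
    cat("AuditReport (", object@mode, " mode)\n", sep = "")
    runs <- object@content$runs
    for (r in runs)
        cat("  run '", r$label, "': threshold = ", format(r$threshold),
            ", strong binders = ", r$binder_count, "\n", sep = "")
    nc <- length(object@content$comparisons)
    if (nc > 0) cat("  ", nc, " cross-run comparison(s)\n", sep = "")
})
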