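.condRoles <- function(x) {
    cd <- colData(x)
    df <- unique(data.frame(condition = cd$condition, role = cd$role,
                            stringsAsFactors = FALSE))
    stats::setNames(df$role, df$condition)
}

#' Accessors for ExpressionStudy design roles
#'
#' \code{healthyControl()} / \code{diseaseControl()} return the label of the
#' single condition carrying that role; \code{treatmentArms()} the remaining
#' condition labels in design order; \code{sampleConditions()} the per-sample
#' condition vector named by sample.
#'
#' @param x an [ExpressionStudy-class].
#' @return character vector(s) of condition labels.
#' @name ExpressionStudy-accessors
NULL

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("healthyControl", "ExpressionStudy", function(x) {
    r <- .condRoles(x); names(r)[r == "healthy_control"]
})

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("diseaseControl", "ExpressionStudy", function(x) {
    r <- .condRoles(x); names(r)[r == "disease_control"]
})

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("treatmentArms", "ExpressionStudy", function(x) {
    r <- .condRoles(x); names(r)[r == "treatment"]
})

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("sampleConditions", "ExpressionStudy", function(x)
    stats::setNames(colData(x)$condition, colnames(x)))

setMethod("show", "ExpressionStudy", function(object) {
    cat(sprintf("ExpressionStudy: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cond <- sampleConditions(object)
    roles <- .condRoles(object)
    for (cn in unique(cond))
        cat(sprintf("  %s (%s): %d samples\n", cn, roles[[cn]],
                    sum(cond == cn)))
})

#' Accessors for AnnotationSet
#'
#' @param x an [AnnotationSet-class].
#' @return \code{geneSets()}: named list of member-gene character vectors;
#'   \code{categoryIds()}: character vector of category identifiers.
#' @name AnnotationSet-accessors
NULL

#' @rdname AnnotationSet-accessors
#' @export
setMethod("geneSets", "AnnotationSet", function(x) x@sets)

#' @rdname AnnotationSet-accessors
#' @export
setMethod("categoryIds", "AnnotationSet", function(x) names(x@sets))

setMethod("show", "AnnotationSet", function(object) {
    sz <- lengths(object@sets)
    cat(sprintf("AnnotationSet '%s': %d categories (sizes %s..%s)\n",
                object@namespace, length(object@sets),
                if (length(sz)) min(sz) else "-",
                if (length(sz)) max(sz) else "-"))
})

setMethod("length", "AnnotationSet", function(x) length(x@sets))

#' Extract differentially expressed genes from a ContrastResult
#'
#' @param x a [ContrastResult-class].
#' @param condition a contrast column label, or NULL for the union over all
#'   conditions.
#' @param direction "both" (default), "up" or "down" relative to the
#'   baseline.
#' @param ... unused.
#' @return sorted character vector of gene identifiers flagged DE.
#' @export
setMethod("deGenes", "ContrastResult",
          function(x, condition = NULL, direction = c("both", "up", "down"),
                   ...) {
    direction <- match.arg(direction)
    conds <- if (is.null(condition)) colnames(x@de) else condition
    bad <- setdiff(conds, colnames(x@de))
    if (length(bad))
        stop("unknown condition(s): ", paste(bad, collapse = ", "))
    keep <- x@de[, conds, drop = FALSE]
    if (direction == "up")
        keep <- keep & x@log2FC[, conds, drop = FALSE] > 0
    else if (direction == "down")
        keep <- keep & x@log2FC[, conds, drop = FALSE] < 0
    sort(rownames(keep)[rowSums(keep) > 0L])
})

setMethod("show", "ContrastResult", function(object) {
    cat(sprintf("ContrastResult vs '%s': %d genes x %d conditions\n",
                object@baseline, nrow(object@log2FC), ncol(object@log2FC)))
    cat(sprintf("  thresholds: |log2FC| >= %g, adjusted p <= %g\n",
                object@lfcThreshold, object@pThreshold))
    for (cn in colnames(object@de))
        cat(sprintf("  %s: %d DE genes\n", cn, sum(object@de[, cn])))
})

setMethod("show", "ClusterAssignment", function(object) {
    cat(sprintf("ClusterAssignment: k = %d over %d genes\n",
                object@k, length(object@labels)))
    if (length(object@silhouetteByK)) {
        best <- names(which.max(object@silhouetteByK))
        cat(sprintf("  mean silhouette at selected k: %.3f\n",
                    suppressWarnings(max(object@silhouetteByK, na.rm = TRUE))))
        cat(sprintf("  search range: k = %s\n",
                    paste(range(as.integer(names(object@silhouetteByK))),
                          collapse = "..")))
    }
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d disease-up, %d disease-down genes\n",
                length(object@diseaseUp), length(object@diseaseDown)))
    for (tr in rownames(object@restorationFraction))
        cat(sprintf("  %s (%s): restore %.3f/%.3f, reverse %.3f, %d altered\n",
                    tr, object@timing[[tr]],
                    object@restorationFraction[tr, "up"],
                    object@restorationFraction[tr, "down"],
                    object@reversalFraction[[tr]],
                    length(object@altered[[tr]])))
})

setMethod("show", "ForestResult", function(object) {
    cat(sprintf("ForestResult (%s level): model %d of %d\n", object@level,
                object@modelIndex, length(object@oobErrors)))
    cat(sprintf("  OOB error %.4f | test accuracy %.4f\n",
                object@oobError, object@testAccuracy))
    cat(sprintf("  %d ranked features; top: %s\n", length(object@importance),
                paste(utils::head(names(object@importance), 3), collapse = ", ")))
})

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable (%s level): %d features x %d samples, %d classes\n",
                object@level, nrow(object@values), ncol(object@values),
                length(unique(object@labels))))
})

setMethod("show", "FrameworkConfig", function(object) {
    cat("FrameworkConfig:\n")
    cat(sprintf("  DE: |log2FC| >= %g, adjusted p <= %g (gene-wise BH: %s)\n",
                object@lfcThreshold, object@pThreshold, object@geneFDR))
    cat(sprintf("  clustering: k in %d..%d\n", object@kRange[1], object@kRange[2]))
    cat(sprintf("  efficiency: %s, min category size %d\n",
                object@efficiencyMode, object@minCategorySize))
    cat(sprintf("  random forest: %d models x %d trees, mtry %d, train %.0f%%\n",
                object@rfModels, object@rfTrees, object@rfMtry,
                100 * object@rfTrainFraction))
})
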