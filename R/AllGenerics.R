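## Accessor generics. Bioconductor-style: users read slots through these,
## never with @.

#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("fieldMeta", function(x) standardGeneric("fieldMeta"))
#' @export
setGeneric("spotLabels", function(x) standardGeneric("spotLabels"))
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))
#' @export
setGeneric("spotMask", function(x) standardGeneric("spotMask"))
#' @export
setGeneric("recruitScore", function(x) standardGeneric("recruitScore"))
#' @export
setGeneric("yellowArea", function(x) standardGeneric("yellowArea"))
#' @export
setGeneric("redArea", function(x) standardGeneric("redArea"))
#' @export
setGeneric("replicateScores", function(x) standardGeneric("replicateScores"))
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @export
setGeneric("levelValues", function(x) standardGeneric("levelValues"))
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))
#' @export
setGeneric("groundTruthCells", function(x) standardGeneric("groundTruthCells"))
#' @export
setGeneric("groundTruthAnchors",
           function(x) standardGeneric("groundTruthAnchors"))
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @describeIn FieldImage-class anchor (RFP) channel matrix
#' @param x object
#' @export
setMethod("redChannel", "FieldImage", function(x) x@red)
#' @describeIn FieldImage-class prey (GFP) channel matrix
#' @export
setMethod("greenChannel", "FieldImage", function(x) x@green)
#' @describeIn FieldImage-class micrometres per pixel
#' @export
setMethod("pixelSize", "FieldImage", function(x) x@pixelSize)
#' @describeIn FieldImage-class acquisition metadata list
#' @export
setMethod("fieldMeta", "FieldImage", function(x) x@meta)

#' @describeIn LabeledSpots-class the integer label image
#' @param x object
#' @export
setMethod("spotLabels", "LabeledSpots", function(x) x@labels)
#' @describeIn LabeledSpots-class the per-spot region table
#' @export
setMethod("spotTable", "LabeledSpots", function(x) x@table)
#' @describeIn LabeledSpots-class number of segmented spots
#' @export
setMethod("nSpots", "LabeledSpots", function(x) nrow(x@table))
#' @describeIn LabeledSpots-class logical foreground mask
#' @export
setMethod("spotMask", "LabeledSpots", function(x) x@labels > 0L)

#' @describeIn RecruitmentResult-class the recruitment score
#' @param x object
#' @export
setMethod("recruitScore", "RecruitmentResult", function(x) x@score)
#' @describeIn RecruitmentResult-class overlap (yellow) area in px^2
#' @export
setMethod("yellowArea", "RecruitmentResult", function(x) x@yellowArea)
#' @describeIn RecruitmentResult-class summed segmented anchor area in px^2
#' @export
setMethod("redArea", "RecruitmentResult", function(x) x@redArea)
#' @describeIn OverlapSet-class overlap (yellow) area in px^2
#' @export
setMethod("yellowArea", "OverlapSet", function(x) x@yellowArea)

#' @describeIn ConditionSummary-class pooled score per biological replicate
#' @param x object
#' @export
setMethod("replicateScores", "ConditionSummary", function(x) x@replicateScores)
#' @describeIn ConditionSummary-class Welch t-test p-value vs the comparison
#' @export
setMethod("pValue", "ConditionSummary", function(x) x@pValue)

#' @describeIn TimeCourse-class sampling times in minutes
#' @param x object
#' @export
setMethod("timePoints", "TimeCourse", function(x) x@timepoints)
#' @describeIn TimeCourse-class detected complex levels
#' @export
setMethod("levelValues", "TimeCourse", function(x) x@levels)
#' @describeIn TimeCourse-class TRUE after normalization to the maximum
#' @export
setMethod("isNormalized", "TimeCourse", function(x) x@normalized)

#' @describeIn RateSeries-class signed inter-measurement rates (1/min)
#' @param x object
#' @export
setMethod("rateValues", "RateSeries", function(x) x@rates)
#' @describeIn RateSeries-class interval midpoints in minutes
#' @export
setMethod("timePoints", "RateSeries", function(x) x@midpoints)

#' @describeIn KineticFit-class named fitted parameters
#' @param x object
#' @export
setMethod("fitParameters", "KineticFit", function(x) x@parameters)

#' @describeIn GroundTruth-class per-cell ground-truth records
#' @param x object
#' @export
setMethod("groundTruthCells", "GroundTruth", function(x) x@cells)
#' @describeIn GroundTruth-class per-anchor ground-truth records
#' @export
setMethod("groundTruthAnchors", "GroundTruth", function(x) x@anchors)

#' @describeIn StdCurve-class amplification efficiency `10^(-1/slope) - 1`
#' @param x object
#' @export
setMethod("efficiency", "StdCurve", function(x) x@efficiency)

## show() methods ------------------------------------------------------------

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@red)
  m <- object@meta
  cat(sprintf("FieldImage %d x %d px (%.3f um/px)\n", d[1], d[2],
              object@pixelSize))
  if (length(m))
    cat("  meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                         collapse = ", "), "\n")
})

setMethod("show", "LabeledSpots", function(object) {
  cat(sprintf("LabeledSpots: %d spot(s) in a %d x %d label image\n",
              nrow(object@table), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "RecruitmentResult", function(object) {
  cat(sprintf(
    "RecruitmentResult (%s): score %.4g [yellow %d px, red %d px]\n",
    object@scope, object@score, as.integer(object@yellowArea),
    as.integer(object@redArea)))
})

setMethod("show", "ConditionSummary", function(object) {
  cat(sprintf("ConditionSummary '%s': mean %.4g +/- %.4g (n = %d)\n",
              object@condition, object@mean, object@sd, object@n))
  if (!is.na(object@reference))
    cat(sprintf("  normalized to '%s': %.4g +/- %.4g\n", object@reference,
                object@normalizedMean, object@normalizedSd))
  if (!is.na(object@comparison))
    cat(sprintf("  Welch t-test vs '%s': p = %.4g\n", object@comparison,
                object@pValue))
})

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse '%s': %d timepoints, %s\n", object@complexId,
              length(object@timepoints),
              if (object@normalized) "normalized (max = 1)" else "raw levels"))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]%s%s\n", object@model,
              if (object@degenerate) " (degenerate)" else "",
              if (!object@converged) " (not converged)" else ""))
  print(signif(object@parameters, 5))
})

setMethod("show", "StdCurve", function(object) {
  cat(sprintf(
    "StdCurve '%s': slope %.4g, intercept %.4g, efficiency %.4g, r2 %.4g\n",
    object@amplicon, object@slope, object@intercept, object@efficiency,
    object@r2))
})

setMethod("show", "OccupancyResult", function(object) {
  cat(sprintf("OccupancyResult: %s / %s, control %s, reference '%s'\n",
              object@target, object@referenceLocus, object@control,
              object@referenceCondition))
  print(object@summary)
})

setMethod("show", "StageLabels", function(object) {
  cat("StageLabels:\n"); print(object@intervals)
})
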