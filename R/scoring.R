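## Recruitment scoring: overlap ("yellow") regions between segmented prey
## spots and segmented anchors, the recruitment score, replicate pooling,
## and condition-level summaries.

#' Overlap regions between prey spots and anchors
#'
#' The yellow mask is the pixelwise AND of the two foreground masks; every
#' (prey label, anchor label) pair sharing at least one pixel is listed.
#'
#' @param prey,anchors [LabeledSpots-class] objects with identical shape.
#' @return an [OverlapSet-class] object.
#' @export
overlapRegions <- function(prey, anchors) {
  pl <- spotLabels(prey); al <- spotLabels(anchors)
  if (!identical(dim(pl), dim(al)))
    stop("prey and anchor label images must have identical shape")
  mask <- pl > 0L & al > 0L
  idx <- which(mask)
  pairs <- unique(data.frame(preyLabel = pl[idx], anchorLabel = al[idx]))
  pairs <- pairs[order(pairs$preyLabel, pairs$anchorLabel), , drop = FALSE]
  rownames(pairs) <- NULL
  new("OverlapSet", mask = mask, yellowArea = as.numeric(length(idx)),
      pairs = pairs)
}

#' Recruitment score of one field
#'
#' The interaction readout: raw green intensity summed over the measured
#' region, divided by the summed area of all segmented anchors. With the
#' default `areaMode = "overlap"` the measured region is the yellow
#' (prey-AND-anchor) pixels; `"whole_spot"` instead uses every pixel of each
#' prey spot that touches an anchor.
#'
#' Prey spots that overlap no anchor contribute nothing, so sparse false
#' positive prey detections barely affect the score. Fields with no
#' segmented anchor are unusable: the function warns and returns `NULL`.
#'
#' @param rawGreen raw green-channel matrix.
#' @param prey,anchors [LabeledSpots-class] objects.
#' @param areaMode `"overlap"` (default) or `"whole_spot"`.
#' @return a [RecruitmentResult-class], or `NULL` for an unusable field.
#' @export
recruitmentScore <- function(rawGreen, prey, anchors,
                             areaMode = c("overlap", "whole_spot")) {
  areaMode <- match.arg(areaMode)
  stopifnot(identical(dim(rawGreen), dim(spotLabels(prey))))
  redArea <- sum(spotLabels(anchors) > 0L)
  if (redArea == 0) {
    warning("field has no segmented anchor (red area 0); no score emitted")
    return(NULL)
  }
  ov <- overlapRegions(prey, anchors)
  measured <- if (areaMode == "overlap") {
    ov@mask
  } else {
    spotLabels(prey) %in% ov@pairs$preyLabel & spotLabels(prey) > 0L
  }
  measured <- matrix(measured, nrow(rawGreen), ncol(rawGreen))
  area <- sum(measured)
  s <- as.numeric(sum(rawGreen[measured]))
  new("RecruitmentResult", yellowArea = as.numeric(area),
      meanGreenInYellow = if (area > 0) s / area else 0,
      sumGreen = s, redArea = as.numeric(redArea),
      score = s / redArea, scope = "field")
}

#' Pool field scores into one replicate-level score
#'
#' Intensities and areas are summed across fields before dividing -- one
#' measurement over all the small regions of all images of a replicate --
#' not averaged per field: `pooled = sum(green over yellow) / sum(red
#' area)`.
#'
#' @param fieldResults list of [RecruitmentResult-class] (NULLs from unusable
#'   fields are dropped).
#' @return a [RecruitmentResult-class] with scope `"replicate"`.
#' @export
poolReplicate <- function(fieldResults) {
  fieldResults <- Filter(Negate(is.null), fieldResults)
  if (!length(fieldResults))
    stop("no usable fields to pool (all had red area 0 or list empty)")
  s <- sum(vapply(fieldResults, function(x) x@sumGreen, numeric(1)))
  ya <- sum(vapply(fieldResults, function(x) x@yellowArea, numeric(1)))
  ra <- sum(vapply(fieldResults, function(x) x@redArea, numeric(1)))
  new("RecruitmentResult", yellowArea = ya,
      meanGreenInYellow = if (ya > 0) s / ya else 0, sumGreen = s,
      redArea = ra, score = s / ra, scope = "replicate")
}

#' Summarize replicate scores for one condition
#'
#' Mean and sample SD over biological replicate scores; optional
#' normalization to a reference condition (replicate scores divided by the
#' reference mean, SD computed after division, no propagation of the
#' reference's own uncertainty); optional two-sided Welch t-test against a
#' comparison condition's replicate scores.
#'
#' @param condition condition id.
#' @param scores numeric replicate-level scores (>= 2 for SD and test).
#' @param reference optional [ConditionSummary-class] to normalize to.
#' @param comparison optional [ConditionSummary-class] to test against.
#' @return a [ConditionSummary-class] object.
#' @export
summarizeCondition <- function(condition, scores, reference = NULL,
                               comparison = NULL) {
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  if (!is.null(comparison) && length(scores) < 2L)
    stop("need >= 2 replicates for a t-test")
  m <- mean(scores); s <- if (length(scores) > 1) stats::sd(scores) else NA_real_
  nm <- NA_real_; ns <- NA_real_; refId <- NA_character_
  if (!is.null(reference)) {
    refId <- reference@condition
    norm <- scores / reference@mean
    nm <- mean(norm); ns <- if (length(norm) > 1) stats::sd(norm) else NA_real_
  }
  pv <- NA_real_; cmpId <- NA_character_
  if (!is.null(comparison)) {
    cmpId <- comparison@condition
    pv <- if (stats::sd(scores) == 0 &&
              stats::sd(comparison@replicateScores) == 0 &&
              isTRUE(all.equal(mean(scores),
                               mean(comparison@replicateScores)))) {
      1  # identical degenerate samples: no evidence of difference
    } else {
      stats::t.test(scores, comparison@replicateScores,
                    var.equal = FALSE)$p.value
    }
  }
  new("ConditionSummary", condition = condition, replicateScores = scores,
      mean = m, sd = s, n = length(scores), normalizedMean = nm,
      normalizedSd = ns, reference = refId, comparison = cmpId, pValue = pv)
}
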