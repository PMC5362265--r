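## Per-channel spot segmentation: Gaussian blur -> white top-hat -> local
## mean threshold -> binary median filter -> area opening -> 8-connected
## labeling, with intensity statistics measured on the raw channel.

#' Construct spot-segmentation parameters
#'
#' @param gaussSigma,tophatRadius,localRadius,offset,offsetNmad,medianRadius,minArea,maxArea
#'   see [SegmentationParams-class].
#' @return a [SegmentationParams-class] object.
#' @export
segmentationParams <- function(gaussSigma = 1, tophatRadius = 8,
                               localRadius = 8, offset = NA_real_,
                               offsetNmad = 5, medianRadius = 1,
                               minArea = 4, maxArea = 200) {
  new("SegmentationParams", gaussSigma = gaussSigma,
      tophatRadius = tophatRadius, localRadius = localRadius,
      offset = offset, offsetNmad = offsetNmad, medianRadius = medianRadius,
      minArea = minArea, maxArea = maxArea)
}

#' Default parameters for the anchor (RFP) channel
#' @return a [SegmentationParams-class] object.
#' @export
anchorSegParams <- function() segmentationParams(gaussSigma = 1)

#' Default parameters for the prey (GFP) channel
#'
#' Slightly stronger smoothing than the anchor channel, to cope with the
#' lower contrast and strong smoothly varying background of the prey signal.
#' @return a [SegmentationParams-class] object.
#' @export
preySegParams <- function() segmentationParams(gaussSigma = 1.5)

#' Noise and background attenuation for one channel
#'
#' Gaussian blurring followed by white top-hat opening with a disk
#' structuring element: the blur suppresses pixel noise, the top-hat removes
#' structures larger than the expected spot size (smooth background). Output
#' is non-negative and pointwise no larger than the blurred input.
#'
#' @param image numeric matrix, finite and non-negative.
#' @param p a [SegmentationParams-class] object.
#' @return preprocessed matrix, same shape.
#' @export
preprocessChannel <- function(image, p) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  validObject(p)
  if (p@tophatRadius >= min(dim(image)) / 2)
    stop("tophatRadius (", p@tophatRadius,
         ") must be smaller than half the image extent")
  whiteTopHat(gaussBlur(image, p@gaussSigma), p@tophatRadius)
}

#' Local mean threshold
#'
#' A pixel is foreground iff its value is strictly greater than the mean of
#' the image over the disk of the given radius centred at that pixel
#' (reflection boundary) plus `offset`. The strict inequality means a
#' constant image yields an empty mask even at offset 0.
#'
#' @param image numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @param offset additive offset in intensity units.
#' @return logical matrix.
#' @export
localMeanThreshold <- function(image, radius, offset) {
  stopifnot(radius >= 1)
  image > diskMean(image, radius) + offset
}

#' Binary cleanup and labeling of a thresholded mask
#'
#' Majority-vote median filtering over a disk neighborhood (radius
#' `medianRadius`; a pixel stays foreground iff foreground pixels are a
#' strict majority of its neighborhood), then 8-connected labeling and area
#' opening (components with area outside `[minArea, maxArea]` are dropped and
#' the survivors relabeled).
#'
#' @param mask logical (or 0/1) matrix.
#' @param p a [SegmentationParams-class] object.
#' @param raw optional raw-channel matrix for the region intensity columns;
#'   defaults to the mask itself (intensity columns then carry no meaning).
#' @return a [LabeledSpots-class] object.
#' @export
cleanMask <- function(mask, p, raw = NULL) {
  validObject(p)
  m <- (mask > 0) * 1
  off <- diskOffsets(p@medianRadius)
  cnt <- shiftWeightedSum(m, off$di, off$dj, rep(1, nrow(off)))
  med <- cnt > nrow(off) / 2
  lab <- labelComponents(med)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= p@minArea & areas <= p@maxArea)
    lab2 <- matrix(0L, nrow(lab), ncol(lab))
    sel <- lab %in% keep
    lab2[sel] <- match(lab[sel], keep)
    lab <- lab2
  }
  if (is.null(raw)) raw <- m
  newLabeledSpots(lab, raw)
}

#' Segment diffraction-limited spots in one channel
#'
#' Full per-channel workflow: [preprocessChannel()], [localMeanThreshold()]
#' (on the preprocessed image), [cleanMask()]. When `p@offset` is `NA` the
#' threshold offset is `p@offsetNmad * stats::mad(preprocessed)`, a robust
#' noise-scaled default. Region intensity statistics are measured on `raw`
#' (the unprocessed channel).
#'
#' @param image numeric matrix to segment.
#' @param raw raw-channel matrix for intensity statistics (default: `image`).
#' @param p a [SegmentationParams-class] object.
#' @return a [LabeledSpots-class] object.
#' @export
segmentSpots <- function(image, raw = image, p = segmentationParams()) {
  stopifnot(identical(dim(image), dim(raw)))
  pre <- preprocessChannel(image, p)
  off <- if (is.na(p@offset)) p@offsetNmad * stats::mad(pre) else p@offset
  mask <- localMeanThreshold(pre, p@localRadius, off)
  cleanMask(mask, p, raw = raw)
}

#' Segment both channels of a field
#'
#' @param field a [FieldImage-class].
#' @param anchorParams,preyParams per-channel [SegmentationParams-class].
#' @return list with [LabeledSpots-class] elements `anchors` and `prey`.
#' @export
segmentField <- function(field, anchorParams = anchorSegParams(),
                         preyParams = preySegParams()) {
  list(anchors = segmentSpots(redChannel(field), p = anchorParams),
       prey = segmentSpots(greenChannel(field), p = preyParams))
}
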