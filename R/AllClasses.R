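#' @import methods
NULL

## ---------------------------------------------------------------------------
## Scene / ground-truth containers (synthetic data)
## ---------------------------------------------------------------------------

#' Parameters of a synthetic two-channel PICT field
#'
#' Describes the generative model for one imaged field of yeast cells: cells
#' are non-overlapping ellipses, each carrying one or two diffraction-limited
#' anchor spots (red channel) and one wide nucleolar blob plus diffuse
#' cytoplasmic signal (green channel). A configurable fraction of cells has
#' prey recruited to its anchors as Gaussian spots in the green channel. Both
#' channels share a smoothly varying background field; noise is Poisson shot
#' noise followed by additive Gaussian read noise.
#'
#' All amplitudes are total integrated photons per placed component;
#' `backgroundMean` and `cellFluor` are photons per pixel.
#'
#' @slot imageShape integer(2), image rows and columns.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot nCells integer, number of cells to place (0 allowed: background only).
#' @slot anchorsPerCell integer, 1 or 2 anchoring platforms per cell.
#' @slot anchorAmplitude numeric, integrated photons per anchor spot (red).
#' @slot preyAmplitudeAtAnchor numeric, integrated photons per recruited prey
#'   spot (green).
#' @slot recruitedFraction numeric in `[0, 1]`, fraction of cells whose prey
#'   co-localizes with its anchors.
#' @slot nucleolusAmplitude numeric, integrated photons of the sub-nuclear
#'   (nucleolar) prey accumulation per cell.
#' @slot psfSigma numeric, Gaussian PSF sigma in pixels.
#' @slot backgroundMean numeric, mean background photons per pixel.
#' @slot backgroundSmoothness numeric, correlation length (px) of the smooth
#'   background field.
#' @slot readNoiseSigma numeric, sd of the additive Gaussian read noise.
#' @slot cellRadius numeric, cell semi-major axis in pixels.
#' @slot cellFluor numeric, diffuse green photons per pixel inside a cell.
#' @slot seed integer, default random seed used when none is supplied.
#' @export
setClass("SceneParams",
  representation(
    imageShape = "integer", pixelSize = "numeric", nCells = "integer",
    anchorsPerCell = "integer", anchorAmplitude = "numeric",
    preyAmplitudeAtAnchor = "numeric", recruitedFraction = "numeric",
    nucleolusAmplitude = "numeric", psfSigma = "numeric",
    backgroundMean = "numeric", backgroundSmoothness = "numeric",
    readNoiseSigma = "numeric", cellRadius = "numeric", cellFluor = "numeric",
    seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (!object@anchorsPerCell %in% c(1L, 2L))
    msg <- c(msg, "anchorsPerCell must be 1 or 2")
  if (object@recruitedFraction < 0 || object@recruitedFraction > 1)
    msg <- c(msg, "recruitedFraction must lie in [0, 1]")
  amps <- c(object@anchorAmplitude, object@preyAmplitudeAtAnchor,
            object@nucleolusAmplitude, object@backgroundMean,
            object@cellFluor, object@readNoiseSigma)
  if (any(amps < 0)) msg <- c(msg, "amplitudes and noise levels must be >= 0")
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
  if (object@backgroundSmoothness <= 0)
    msg <- c(msg, "backgroundSmoothness must be > 0")
  if (object@cellRadius <= 0) msg <- c(msg, "cellRadius must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated field
#'
#' @slot cells data.frame with one row per cell: `cell`, `row`, `col`
#'   (centre), `theta` (anchor axis orientation, rad), `recruited` (logical),
#'   `nucRow`, `nucCol` (nucleolus centre).
#' @slot anchors data.frame with one row per anchor: `cell`, `anchor`, `row`,
#'   `col`, `expectedGreen` (noise-free expected mean green intensity over the
#'   anchor footprint).
#' @slot expectedScore numeric, analytic expected recruitment score for the
#'   generating parameters (see [expectedScore()]).
#' @slot maskRadius numeric, radius (px) of the true anchor-footprint disks.
#' @slot photonTotals named numeric, analytic expected photon sums per channel
#'   with noise off (for photon-accounting checks).
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", anchors = "data.frame",
                 expectedScore = "numeric", maskRadius = "numeric",
                 photonTotals = "numeric")
)

setValidity("GroundTruth", function(object) {
  if (length(object@expectedScore) == 1L && object@expectedScore < 0)
    return("expectedScore must be >= 0")
  TRUE
})

#' One imaged PICT field: paired red/green channels plus metadata
#'
#' @slot red numeric matrix, anchor (RFP) channel intensities.
#' @slot green numeric matrix, prey (GFP) channel intensities, same shape.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot meta list with elements such as `strain`, `condition`, `replicate`,
#'   `field`, `timepoint`.
#' @export
setClass("FieldImage",
  representation(red = "matrix", green = "matrix", pixelSize = "numeric",
                 meta = "list")
)

setValidity("FieldImage", function(object) {
  msg <- character()
  if (!identical(dim(object@red), dim(object@green)))
    msg <- c(msg, "red and green channels must have identical shape")
  if (any(object@red < 0) || any(object@green < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic kinetic time course
#'
#' The initiation-competent complex (Pol I--Rrn3) decays exponentially,
#' `v(t) = offset + amplitude * exp(-t / tau)`; the inactive homodimer rises
#' as a 4-parameter logistic `lo + (hi - lo) / (1 + exp(-s * (t - t50)))`.
#' Multiplicative Gaussian measurement noise is applied to both.
#'
#' @slot rrn3Decay named numeric: `amplitude`, `tau` (min), `offset`.
#' @slot dimerRise named numeric: `lo`, `hi`, `t50` (min), `steepness` (1/min).
#' @slot measurementNoiseSd numeric, sd of the multiplicative noise (fraction).
#' @slot timepoints numeric, strictly increasing sampling times in minutes.
#' @export
setClass("KineticParams",
  representation(rrn3Decay = "numeric", dimerRise = "numeric",
                 measurementNoiseSd = "numeric", timepoints = "numeric")
)

setValidity("KineticParams", function(object) {
  msg <- character()
  need1 <- c("amplitude", "tau", "offset")
  need2 <- c("lo", "hi", "t50", "steepness")
  if (!all(need1 %in% names(object@rrn3Decay)))
    msg <- c(msg, "rrn3Decay needs amplitude, tau, offset")
  else if (object@rrn3Decay[["tau"]] <= 0) msg <- c(msg, "tau must be > 0")
  if (!all(need2 %in% names(object@dimerRise)))
    msg <- c(msg, "dimerRise needs lo, hi, t50, steepness")
  else {
    if (object@dimerRise[["steepness"]] <= 0)
      msg <- c(msg, "steepness must be > 0")
    if (object@dimerRise[["lo"]] > object@dimerRise[["hi"]])
      msg <- c(msg, "asymptotes must be ordered lo <= hi")
  }
  if (object@measurementNoiseSd < 0) msg <- c(msg, "noise sd must be >= 0")
  if (length(object@timepoints) < 2L || any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing, length >= 2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Segmentation containers
## ---------------------------------------------------------------------------

#' Per-channel spot-segmentation parameters
#'
#' The workflow is: Gaussian blur (`gaussSigma`), white top-hat with a disk
#' structuring element (`tophatRadius`), local mean threshold (disk radius
#' `localRadius`, additive `offset`), then binary median filtering
#' (`medianRadius`) and area opening (`minArea`..`maxArea`). An `NA` offset
#' means "automatic": `offsetNmad` times the robust noise estimate
#' (`stats::mad`) of the preprocessed image.
#'
#' @slot gaussSigma numeric, blur sigma (px).
#' @slot tophatRadius numeric, disk radius (px) of the top-hat SE.
#' @slot localRadius numeric, disk radius (px) of the local mean.
#' @slot offset numeric, additive threshold offset (intensity units) or `NA`.
#' @slot offsetNmad numeric, multiplier for the automatic offset.
#' @slot medianRadius numeric, disk radius (px) of the binary median filter.
#' @slot minArea numeric, minimum surviving region area (px^2).
#' @slot maxArea numeric, maximum surviving region area (px^2).
#' @export
setClass("SegmentationParams",
  representation(gaussSigma = "numeric", tophatRadius = "numeric",
                 localRadius = "numeric", offset = "numeric",
                 offsetNmad = "numeric", medianRadius = "numeric",
                 minArea = "numeric", maxArea = "numeric")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@gaussSigma <= 0) msg <- c(msg, "gaussSigma must be > 0")
  if (object@tophatRadius < 1) msg <- c(msg, "tophatRadius must be >= 1")
  if (object@localRadius < 1) msg <- c(msg, "localRadius must be >= 1")
  if (object@medianRadius < 1) msg <- c(msg, "medianRadius must be >= 1")
  if (!(object@minArea > 0 && object@minArea < object@maxArea))
    msg <- c(msg, "need 0 < minArea < maxArea")
  if (length(msg)) msg else TRUE
})

#' Labeled spots from segmenting one channel
#'
#' @slot labels integer matrix, same shape as the input image; 0 = background,
#'   positive integers = 8-connected spot labels.
#' @slot table data.frame with one row per label: `label`, `area`,
#'   `centroidRow`, `centroidCol`, `sumRaw`, `meanRaw`, `maxRow`, `maxCol`
#'   (brightest raw pixel).
#' @export
setClass("LabeledSpots",
  representation(labels = "matrix", table = "data.frame")
)

setValidity("LabeledSpots", function(object) {
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (!identical(labs, sort(as.integer(object@table$label))))
    return("region table rows must correspond one-to-one with labels")
  TRUE
})

## ---------------------------------------------------------------------------
## Recruitment scoring containers
## ---------------------------------------------------------------------------

#' Prey/anchor overlap set ("yellow" pixels)
#'
#' @slot mask logical matrix of overlap (yellow) pixels.
#' @slot yellowArea numeric, number of TRUE pixels.
#' @slot pairs data.frame of contributing `(preyLabel, anchorLabel)` pairs.
#' @export
setClass("OverlapSet",
  representation(mask = "matrix", yellowArea = "numeric", pairs = "data.frame")
)

setValidity("OverlapSet", function(object) {
  if (sum(object@mask) != object@yellowArea)
    return("yellowArea must equal the number of TRUE mask pixels")
  TRUE
})

#' Recruitment score of a field or pooled replicate
#'
#' `score = sumGreen / redArea`, where `sumGreen` is the raw green intensity
#' summed over the measured (yellow) pixels and `redArea` the summed area of
#' all segmented anchors. Equivalently mean green in yellow times yellow area
#' over red area; `score * redArea == sumGreen` holds exactly.
#'
#' @slot yellowArea numeric, measured-region area (px^2).
#' @slot meanGreenInYellow numeric, mean raw green over the measured region
#'   (0 when the region is empty).
#' @slot sumGreen numeric, raw green summed over the measured region.
#' @slot redArea numeric, summed segmented anchor area (px^2).
#' @slot score numeric, the recruitment score.
#' @slot scope character, `"field"` or `"replicate"`.
#' @export
setClass("RecruitmentResult",
  representation(yellowArea = "numeric", meanGreenInYellow = "numeric",
                 sumGreen = "numeric", redArea = "numeric", score = "numeric",
                 scope = "character")
)

setValidity("RecruitmentResult", function(object) {
  msg <- character()
  if (object@score < 0) msg <- c(msg, "score must be >= 0")
  if (object@yellowArea == 0 && object@score != 0)
    msg <- c(msg, "empty overlap must give score 0")
  if (abs(object@score * object@redArea - object@sumGreen) >
      1e-9 * max(1, abs(object@sumGreen)))
    msg <- c(msg, "identity score * redArea == sumGreen violated")
  if (!object@scope %in% c("field", "replicate"))
    msg <- c(msg, "scope must be 'field' or 'replicate'")
  if (length(msg)) msg else TRUE
})

#' Condition-level summary of replicate recruitment scores
#'
#' @slot condition character, condition id.
#' @slot replicateScores numeric, one pooled score per biological replicate.
#' @slot mean,sd numeric, mean and sample SD over replicates.
#' @slot n integer, number of replicates.
#' @slot normalizedMean,normalizedSd numeric, after division by the reference
#'   condition mean (`NA` when no reference given).
#' @slot reference,comparison character, ids of the reference and comparison
#'   conditions (`NA` when absent).
#' @slot pValue numeric, two-sided Welch t-test p-value vs the comparison
#'   condition's replicate scores (`NA` when no comparison given).
#' @export
setClass("ConditionSummary",
  representation(condition = "character", replicateScores = "numeric",
                 mean = "numeric", sd = "numeric", n = "integer",
                 normalizedMean = "numeric", normalizedSd = "numeric",
                 reference = "character", comparison = "character",
                 pValue = "numeric")
)

setValidity("ConditionSummary", function(object) {
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Localization containers
## ---------------------------------------------------------------------------

#' A pair of anchoring platforms in one cell
#'
#' @slot labels integer(2), the two anchor labels.
#' @slot points numeric 2x2 matrix, brightest-pixel (row, col) per anchor.
#' @slot separation numeric, centre separation in micrometres.
#' @export
setClass("AnchorPair",
  representation(labels = "integer", points = "matrix", separation = "numeric")
)

setValidity("AnchorPair", function(object) {
  if (length(object@labels) != 2L || object@labels[1] == object@labels[2])
    return("an anchor pair needs two distinct labels")
  TRUE
})

#' Classification of prey localization from an inter-anchor profile
#'
#' @slot redProfile,greenProfile numeric, intensity sampled along the line
#'   joining the two anchors' brightest pixels (~1 px spacing).
#' @slot redPeaks integer(2), profile indices of the two anchor peaks.
#' @slot greenPeak integer, profile index of the green maximum.
#' @slot greenPeakFraction numeric, green peak position as a fraction of the
#'   inter-peak distance (0 = first anchor, 1 = second).
#' @slot prominence numeric, green peak height above the profile median.
#' @slot locClass character, one of `"nuclear"`, `"non_nuclear"`, `"ambiguous"`.
#' @slot reason character, reason code for ambiguous calls (`""` otherwise).
#' @export
setClass("ProfileClassification",
  representation(redProfile = "numeric", greenProfile = "numeric",
                 redPeaks = "integer", greenPeak = "integer",
                 greenPeakFraction = "numeric", prominence = "numeric",
                 locClass = "character", reason = "character")
)

setValidity("ProfileClassification", function(object) {
  if (!object@locClass %in% c("nuclear", "non_nuclear", "ambiguous"))
    return("class must be nuclear, non_nuclear or ambiguous")
  TRUE
})

## ---------------------------------------------------------------------------
## Dynamics containers
## ---------------------------------------------------------------------------

#' A complex-level time course
#'
#' @slot complexId character, e.g. `"PolI-Rrn3"` or `"PolI-dimer"`.
#' @slot timepoints numeric, minutes, strictly increasing.
#' @slot levels numeric, non-negative detected levels.
#' @slot normalized logical, TRUE after division by the maximum measurement.
#' @export
setClass("TimeCourse",
  representation(complexId = "character", timepoints = "numeric",
                 levels = "numeric", normalized = "logical")
)

setValidity("TimeCourse", function(object) {
  msg <- character()
  if (length(object@timepoints) != length(object@levels))
    msg <- c(msg, "timepoints and levels must have equal length")
  if (any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (any(object@levels < 0)) msg <- c(msg, "levels must be >= 0")
  if (isTRUE(object@normalized) && length(object@levels) &&
      abs(max(object@levels) - 1) > 0)
    msg <- c(msg, "normalized series must have max level exactly 1")
  if (length(msg)) msg else TRUE
})

#' Inter-measurement assembly/disassembly rates
#'
#' Forward differences between consecutive measurements: positive values are
#' assembly, negative disassembly.
#'
#' @slot midpoints numeric, interval midpoints (min).
#' @slot rates numeric, signed level change per minute.
#' @slot dt numeric, interval widths (min).
#' @export
setClass("RateSeries",
  representation(midpoints = "numeric", rates = "numeric", dt = "numeric")
)

setValidity("RateSeries", function(object) {
  if (length(object@midpoints) != length(object@rates) ||
      length(object@rates) != length(object@dt))
    return("midpoints, rates and dt must have equal length")
  TRUE
})

#' Stage labels of the kinetic response
#'
#' @slot intervals data.frame: `start`, `end` (min), `stage`.
#' @slot boundaries numeric, stage-change times (subset of the timepoints).
#' @export
setClass("StageLabels",
  representation(intervals = "data.frame", boundaries = "numeric")
)

#' A descriptive kinetic fit
#'
#' @slot model character, `"exponential_decay"` or `"logistic"`.
#' @slot parameters named numeric.
#' @slot rss numeric, residual sum of squares.
#' @slot converged logical.
#' @slot degenerate logical, TRUE when the data carry no usable signal
#'   (e.g. a constant series).
#' @export
setClass("KineticFit",
  representation(model = "character", parameters = "numeric", rss = "numeric",
                 converged = "logical", degenerate = "logical")
)

setValidity("KineticFit", function(object) {
  if (!object@model %in% c("exponential_decay", "logistic"))
    return("model must be exponential_decay or logistic")
  TRUE
})

## ---------------------------------------------------------------------------
## ChIP-qPCR containers
## ---------------------------------------------------------------------------

#' qPCR standard curve from a serial dilution
#'
#' @slot amplicon character.
#' @slot slope numeric, Ct per log10 relative quantity (negative).
#' @slot intercept numeric, Ct at log10 quantity 0.
#' @slot efficiency numeric, `10^(-1/slope) - 1`.
#' @slot r2 numeric, coefficient of determination.
#' @export
setClass("StdCurve",
  representation(amplicon = "character", slope = "numeric",
                 intercept = "numeric", efficiency = "numeric", r2 = "numeric")
)

setValidity("StdCurve", function(object) {
  msg <- character()
  if (object@slope >= 0) msg <- c(msg, "slope must be < 0")
  if (object@efficiency <= 0 || object@efficiency > 1.1)
    msg <- c(msg, "efficiency must lie in (0, 1.1]")
  if (object@r2 < 0 || object@r2 > 1) msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Relative ChIP occupancy after the full normalization chain
#'
#' Per condition and biological replicate: IP/input ratio at the target
#' locus, divided by the same ratio at the non-transcribed control region,
#' divided by the same control-normalized ratio at the reference locus (5S);
#' fold change relative to a reference condition.
#'
#' @slot perReplicate data.frame: `condition`, `replicate`, `occupancy`.
#' @slot summary data.frame: `condition`, `mean`, `sd`, `n`, `fold`.
#' @slot target,control,referenceLocus,referenceCondition character.
#' @export
setClass("OccupancyResult",
  representation(perReplicate = "data.frame", summary = "data.frame",
                 target = "character", control = "character",
                 referenceLocus = "character", referenceCondition = "character")
)

setValidity("OccupancyResult", function(object) {
  if (any(object@perReplicate$occupancy <= 0))
    return("occupancies must be > 0")
  TRUE
})
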