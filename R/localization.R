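## Nuclear vs non-nuclear classification of recruited prey from intensity
## profiles along the line joining two anchoring platforms. In cells with
## two spindle pole bodies the nucleus lies between them, so a prey peak
## strictly between the two anchor peaks is scored nuclear.

#' Pair anchors into two-platform cells
#'
#' Greedily pairs mutually nearest anchors (by brightest-pixel distance)
#' whose separation falls within `[dMin, dMax]` micrometres; pairs are
#' accepted in order of increasing separation, each anchor joins at most one
#' pair, and unpaired anchors are dropped.
#'
#' @param anchors a [LabeledSpots-class] of segmented anchors.
#' @param pixelSize micrometres per pixel.
#' @param dMin,dMax allowed separation window in micrometres (defaults 1 and
#'   4, typical spindle-pole-body separations).
#' @return list of [AnchorPair-class] objects (possibly empty).
#' @export
pairAnchors <- function(anchors, pixelSize, dMin = 1, dMax = 4) {
  tb <- spotTable(anchors)
  n <- nrow(tb)
  if (n < 2L) return(list())
  pts <- cbind(tb$maxRow, tb$maxCol)
  D <- as.matrix(stats::dist(pts)) * pixelSize
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  used <- rep(FALSE, n)
  cand <- which(nn[nn] == seq_len(n) & seq_len(n) < nn)  # mutual NN, once
  cand <- cand[order(D[cbind(cand, nn[cand])])]
  out <- list()
  for (i in cand) {
    j <- nn[i]
    if (used[i] || used[j]) next
    sep <- D[i, j]
    if (sep < dMin || sep > dMax) next
    used[c(i, j)] <- TRUE
    out[[length(out) + 1L]] <- new("AnchorPair",
      labels = as.integer(tb$label[c(i, j)]),
      points = matrix(c(pts[i, ], pts[j, ]), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, c("row", "col"))),
      separation = sep)
  }
  out
}

#' Intensity profile along a line segment
#'
#' Samples bilinear-interpolated intensity at approximately 1 px spacing
#' along the segment `p0 -> p1`, endpoints included (`round(dist) + 1`
#' equally spaced stations, so the profile of the reversed segment is the
#' reversed profile).
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric (row, col) endpoints, distinct and inside the image.
#' @return numeric vector of sampled intensities.
#' @export
lineProfile <- function(image, p0, p1) {
  stopifnot(length(p0) == 2L, length(p1) == 2L)
  if (all(p0 == p1)) stop("profile endpoints must differ")
  nr <- nrow(image); nc <- ncol(image)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc)
      stop("profile endpoint (", p[1], ", ", p[2], ") outside the image")
  d <- sqrt(sum((p1 - p0)^2))
  nSteps <- max(1L, as.integer(round(d)))
  tt <- seq(0, 1, length.out = nSteps + 1L)
  r <- p0[1] + tt * (p1[1] - p0[1])
  cc <- p0[2] + tt * (p1[2] - p0[2])
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    image[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Red and green profiles between an anchor pair
#'
#' Extracts both channels' profiles along the line joining the pair's
#' brightest pixels, after subtracting each channel's field median
#' (background subtraction; configurable off).
#'
#' @param field a [FieldImage-class].
#' @param pair an [AnchorPair-class].
#' @param subtractBackground logical; subtract the per-channel field median
#'   before profiling (default TRUE).
#' @return list with numeric vectors `red` and `green`.
#' @export
profileAnchorPair <- function(field, pair, subtractBackground = TRUE) {
  r <- redChannel(field); g <- greenChannel(field)
  if (subtractBackground) {
    r <- r - stats::median(r); g <- g - stats::median(g)
  }
  p0 <- pair@points[1, ]; p1 <- pair@points[2, ]
  list(red = lineProfile(r, p0, p1), green = lineProfile(g, p0, p1))
}

#' Classify prey localization from inter-anchor profiles
#'
#' The two red peaks are the maxima within 20% of the profile length of each
#' end. The green peak is the global maximum; its prominence is its height
#' above the green profile's median. The call is `nuclear` iff the green
#' peak lies in the open interval between the red peaks shrunk by `margin`
#' times the inter-peak distance on each side and its prominence exceeds
#' `prominenceNmad * mad(green profile)`; `non_nuclear` iff the prominent
#' peak falls within the margin of a red peak or outside the interval;
#' `ambiguous` otherwise (low prominence, or unresolved red peaks).
#'
#' @param redProfile,greenProfile numeric vectors of equal length >= 5.
#' @param margin fraction of the inter-peak distance excluded at each end
#'   (default 0.15).
#' @param prominenceNmad prominence threshold in units of the green
#'   profile's MAD (default 3).
#' @return a [ProfileClassification-class] object.
#' @export
classifyLocalization <- function(redProfile, greenProfile, margin = 0.15,
                                 prominenceNmad = 3) {
  n <- length(redProfile)
  stopifnot(n == length(greenProfile), n >= 5L)
  endw <- max(1L, floor(0.2 * n))
  left <- which.max(redProfile[1:endw])
  right <- n - endw + which.max(redProfile[(n - endw + 1L):n])
  base <- list(redProfile = redProfile, greenProfile = greenProfile,
               redPeaks = as.integer(c(left, right)))
  gp <- which.max(greenProfile)
  prom <- greenProfile[gp] - stats::median(greenProfile)
  if (right - left < 2L)
    return(new("ProfileClassification", redProfile = redProfile,
               greenProfile = greenProfile,
               redPeaks = as.integer(c(left, right)), greenPeak = as.integer(gp),
               greenPeakFraction = NA_real_, prominence = prom,
               locClass = "ambiguous", reason = "red_peaks_unresolved"))
  frac <- (gp - left) / (right - left)
  thr <- prominenceNmad * stats::mad(greenProfile)
  cls <- if (prom <= thr) "ambiguous"
    else if (frac > margin && frac < 1 - margin) "nuclear"
    else "non_nuclear"
  new("ProfileClassification", redProfile = redProfile,
      greenProfile = greenProfile, redPeaks = as.integer(c(left, right)),
      greenPeak = as.integer(gp), greenPeakFraction = frac,
      prominence = prom, locClass = cls,
      reason = if (cls == "ambiguous") "low_prominence" else "")
}

#' Per-strain nuclear fraction from stored classifications
#'
#' @param classes character vector of classes (or list of
#'   [ProfileClassification-class]).
#' @param dropAmbiguous logical; exclude ambiguous calls from the
#'   denominator (default TRUE).
#' @return fraction of nuclear calls.
#' @export
nuclearFraction <- function(classes, dropAmbiguous = TRUE) {
  if (is.list(classes))
    classes <- vapply(classes, function(x) x@locClass, character(1))
  if (dropAmbiguous) classes <- classes[classes != "ambiguous"]
  if (!length(classes)) return(NA_real_)
  mean(classes == "nuclear")
}
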