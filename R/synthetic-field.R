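## Synthetic two-channel PICT fields with known ground truth.
##
## The generative model (see the methods vignette for rationale):
##   cells    : non-overlapping ellipses (axis ratio 0.85), centres placed by
##              rejection sampling with a 1.2 * cellRadius border margin;
##   anchors  : 1 or 2 isotropic Gaussian spots (sigma = psfSigma) per cell at
##              +/- 0.5 * cellRadius from the centre along a random axis;
##   green    : diffuse signal inside the cell, one wide nucleolar Gaussian
##              blob (sigma = 0.35 * cellRadius) offset perpendicular to the
##              anchor axis, and -- in recruited cells -- prey spots centred
##              on the anchors;
##   background: one smooth Gaussian random field shared by both channels,
##              scaled to mean backgroundMean with 20% spatial CV;
##   noise    : Poisson on the expected photons, then additive Gaussian read
##              noise, clipped at zero.

.bgCV <- 0.2          # spatial coefficient of variation of the background
.axisRatio <- 0.85    # ellipse minor/major axis ratio
.nucSigmaFrac <- 0.35 # nucleolus sigma as a fraction of cellRadius
.anchorOffsetFrac <- 0.5

#' Construct scene parameters for the synthetic field generator
#'
#' Defaults emulate the original assay's imaging design: fields of budding
#' yeast with one or two diffraction-limited anchors per cell, a bright
#' sub-nuclear (nucleolar) prey accumulation, a strong smoothly varying
#' background, and shot plus read noise at 100 nm/px sampling.
#'
#' @param imageShape integer(2) image rows, cols.
#' @param pixelSize um per pixel.
#' @param nCells number of cells.
#' @param anchorsPerCell 1 or 2.
#' @param anchorAmplitude integrated photons per anchor spot.
#' @param preyAmplitudeAtAnchor integrated photons per recruited prey spot.
#' @param recruitedFraction fraction of cells with prey at their anchors.
#' @param nucleolusAmplitude integrated photons of the nucleolar blob.
#' @param psfSigma PSF sigma, px.
#' @param backgroundMean mean background photons per px.
#' @param backgroundSmoothness background correlation length, px.
#' @param readNoiseSigma additive read-noise sd.
#' @param cellRadius cell semi-major axis, px.
#' @param cellFluor diffuse green photons per px inside cells.
#' @param seed default integer seed.
#' @return a [SceneParams-class] object.
#' @examples
#' sp <- sceneParams(imageShape = c(96, 96), nCells = 2, cellRadius = 12)
#' sim <- simulateField(sp, seed = 1)
#' @export
sceneParams <- function(imageShape = c(256L, 256L), pixelSize = 0.1,
                        nCells = 6L, anchorsPerCell = 2L,
                        anchorAmplitude = 5000, preyAmplitudeAtAnchor = 2000,
                        recruitedFraction = 0.5, nucleolusAmplitude = 20000,
                        psfSigma = 1.5, backgroundMean = 100,
                        backgroundSmoothness = 40, readNoiseSigma = 2,
                        cellRadius = 20, cellFluor = 20, seed = 1L) {
  new("SceneParams", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, nCells = as.integer(nCells),
      anchorsPerCell = as.integer(anchorsPerCell),
      anchorAmplitude = anchorAmplitude,
      preyAmplitudeAtAnchor = preyAmplitudeAtAnchor,
      recruitedFraction = recruitedFraction,
      nucleolusAmplitude = nucleolusAmplitude, psfSigma = psfSigma,
      backgroundMean = backgroundMean,
      backgroundSmoothness = backgroundSmoothness,
      readNoiseSigma = readNoiseSigma, cellRadius = cellRadius,
      cellFluor = cellFluor, seed = as.integer(seed))
}

## Discrete spot kernel: Gaussian sampled at integer offsets -h:h relative to
## the sub-pixel centre (dr, dc), normalized to sum 1 so a spot deposits
## exactly `amplitude` photons inside its window.
.spotKernel <- function(dr, dc, sigma, h = ceiling(4 * sigma)) {
  i <- (-h):h
  kr <- exp(-((i - dr)^2) / (2 * sigma^2))
  kc <- exp(-((i - dc)^2) / (2 * sigma^2))
  K <- outer(kr, kc)
  K / sum(K)
}

## Add a Gaussian spot of integrated `amp` photons at (row, col) (sub-pixel).
.addSpot <- function(img, row, col, sigma, amp) {
  h <- ceiling(4 * sigma)
  r0 <- round(row); c0 <- round(col)
  K <- .spotKernel(row - r0, col - c0, sigma, h)
  rr <- (r0 - h):(r0 + h); cc <- (c0 - h):(c0 + h)
  rok <- rr >= 1 & rr <= nrow(img); cok <- cc >= 1 & cc <= ncol(img)
  img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] + amp * K[rok, cok]
  img
}

## Smooth background field: white noise blurred at the correlation length,
## standardized, then scaled to mean `bg` with spatial CV .bgCV.
.backgroundField <- function(shape, bg, smoothness) {
  if (bg <= 0) return(matrix(0, shape[1], shape[2]))
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  z <- gaussBlur(z, smoothness)
  z <- (z - mean(z)) / stats::sd(z)
  pmax(bg * (1 + .bgCV * z), 0)
}

## Indicator of an ellipse (semi-axes a, b = .axisRatio * a, orientation phi).
.paintEllipse <- function(img, row, col, a, phi, value) {
  b <- .axisRatio * a
  rr <- max(1, floor(row - a)):min(nrow(img), ceiling(row + a))
  cc <- max(1, floor(col - a)):min(ncol(img), ceiling(col + a))
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  x <- cos(phi) * dr + sin(phi) * dc
  y <- -sin(phi) * dr + cos(phi) * dc
  inside <- (x / a)^2 + (y / b)^2 <= 1
  img[rr, cc] <- img[rr, cc] + value * inside
  img
}

.placeCells <- function(params) {
  nr <- params@imageShape[1]; nc <- params@imageShape[2]
  margin <- 1.2 * params@cellRadius
  if (params@nCells > 0 && (nr - 2 * margin < 1 || nc - 2 * margin < 1))
    stop("image too small to place cells: need a border margin of ",
         "1.2 * cellRadius = ", margin, " px on each side")
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < params@nCells) {
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    ok <- !nrow(centers) ||
      all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= 2 * params@cellRadius)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 5000L)
      stop("image too small to place ", params@nCells,
           " non-overlapping cells of radius ", params@cellRadius, " px")
  }
  centers
}

#' Simulate one two-channel PICT field
#'
#' Draws cell/anchor geometry, renders noise-free red and green channels from
#' the generative model, then applies Poisson shot noise and Gaussian read
#' noise (clipped at zero). Identical `(params, seed)` give bit-identical
#' output.
#'
#' @param params a [SceneParams-class] object.
#' @param seed integer seed (default `params@seed`).
#' @param noise logical; `FALSE` renders the noise-free expectation (and a
#'   flat background at `backgroundMean`, its expected value).
#' @param meta list of acquisition metadata attached to the field.
#' @return list with elements `field` ([FieldImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
simulateField <- function(params, seed = params@seed, noise = TRUE,
                          meta = list()) {
  validObject(params)
  set.seed(as.integer(seed))
  nr <- params@imageShape[1]; nc <- params@imageShape[2]
  red <- matrix(0, nr, nc); green <- matrix(0, nr, nc)

  centers <- .placeCells(params)
  n <- params@nCells
  theta <- if (n) stats::runif(n, 0, 2 * pi) else numeric(0)
  phi <- if (n) stats::runif(n, 0, pi) else numeric(0)
  nRec <- round(params@recruitedFraction * n)
  recruited <- rep(FALSE, n)
  if (nRec > 0) recruited[sample.int(n, nRec)] <- TRUE

  off <- .anchorOffsetFrac * params@cellRadius
  nucSigma <- .nucSigmaFrac * params@cellRadius
  cells <- data.frame(cell = seq_len(n),
                      row = centers[, 1][seq_len(n)],
                      col = centers[, 2][seq_len(n)],
                      theta = theta, recruited = recruited,
                      nucRow = numeric(n), nucCol = numeric(n))
  anchors <- data.frame(cell = integer(0), anchor = integer(0),
                        row = numeric(0), col = numeric(0))
  for (i in seq_len(n)) {
    u <- c(cos(theta[i]), sin(theta[i]))
    v <- c(-u[2], u[1])
    pts <- if (params@anchorsPerCell == 2L)
      rbind(centers[i, ] + off * u, centers[i, ] - off * u)
    else
      rbind(centers[i, ] + off * u)
    nucP <- centers[i, ] + off * v
    cells$nucRow[i] <- nucP[1]; cells$nucCol[i] <- nucP[2]
    for (a in seq_len(nrow(pts))) {
      anchors <- rbind(anchors, data.frame(cell = i, anchor = a,
                                           row = pts[a, 1], col = pts[a, 2]))
      red <- .addSpot(red, pts[a, 1], pts[a, 2], params@psfSigma,
                      params@anchorAmplitude)
      if (recruited[i])
        green <- .addSpot(green, pts[a, 1], pts[a, 2], params@psfSigma,
                          params@preyAmplitudeAtAnchor)
    }
    if (params@cellFluor > 0)
      green <- .paintEllipse(green, centers[i, 1], centers[i, 2],
                             params@cellRadius, phi[i], params@cellFluor)
    if (params@nucleolusAmplitude > 0)
      green <- .addSpot(green, nucP[1], nucP[2], nucSigma,
                        params@nucleolusAmplitude)
  }

  if (noise) {
    bg <- .backgroundField(c(nr, nc), params@backgroundMean,
                           params@backgroundSmoothness)
  } else {
    bg <- matrix(params@backgroundMean, nr, nc)
  }
  red <- red + bg; green <- green + bg

  if (noise) {
    red <- stats::rpois(nr * nc, pmax(red, 0)) +
      stats::rnorm(nr * nc, 0, params@readNoiseSigma)
    green <- stats::rpois(nr * nc, pmax(green, 0)) +
      stats::rnorm(nr * nc, 0, params@readNoiseSigma)
    red <- matrix(pmax(red, 0), nr, nc)
    green <- matrix(pmax(green, 0), nr, nc)
  }

  es <- if (n > 0) expectedScore(params) else 0
  stats_ <- if (n > 0) .footprintStats(params) else NULL
  if (n > 0) {
    anchors$expectedGreen <- params@backgroundMean + params@cellFluor +
      params@nucleolusAmplitude * stats_$nucDensity +
      ifelse(cells$recruited[anchors$cell],
             params@preyAmplitudeAtAnchor * stats_$fIn / stats_$diskArea, 0)
  } else anchors$expectedGreen <- numeric(0)

  ellArea <- pi * params@cellRadius^2 * .axisRatio
  photonTotals <- c(
    red = n * params@anchorsPerCell * params@anchorAmplitude +
      params@backgroundMean * nr * nc,
    green = params@backgroundMean * nr * nc + n * params@cellFluor * ellArea +
      n * params@nucleolusAmplitude +
      nRec * params@anchorsPerCell * params@preyAmplitudeAtAnchor)

  field <- new("FieldImage", red = red, green = green,
               pixelSize = params@pixelSize, meta = meta)
  truth <- new("GroundTruth", cells = cells, anchors = anchors,
               expectedScore = es,
               maskRadius = ceiling(2 * params@psfSigma),
               photonTotals = photonTotals)
  list(field = field, truth = truth)
}

#' Deterministic per-field seed stream
#'
#' Hashes `(baseSeed, replicate, field)` into a 31-bit seed. The mapping is
#' fixed and documented: `(baseSeed * 100003 + replicate * 10007 + field * 101)
#' mod 2147483629`.
#'
#' @param baseSeed,replicate,field integers.
#' @return integer seed.
#' @export
fieldSeed <- function(baseSeed, replicate, field) {
  as.integer((as.numeric(baseSeed) * 100003 + replicate * 10007 +
                field * 101) %% 2147483629)
}

#' Simulate a full condition (replicates x fields)
#'
#' Emulates the replicate design of the assay: biological replicates, each
#' imaged in several fields of view. Per-field seeds derive deterministically
#' from `baseSeed` via [fieldSeed()]. Optional replicate-level biological
#' variation multiplies `preyAmplitudeAtAnchor` by
#' `exp(rnorm(1, 0, replicateCv))` per replicate.
#'
#' @param params a [SceneParams-class] object.
#' @param nReplicates number of biological replicates (default 3).
#' @param nFields fields of view per replicate (default 6).
#' @param baseSeed integer base seed.
#' @param replicateCv log-normal CV of the replicate effect (default 0).
#' @param condition condition label recorded in each field's metadata.
#' @return list of replicates; each replicate is a list of `simulateField()`
#'   results.
#' @export
simulateCondition <- function(params, nReplicates = 3L, nFields = 6L,
                              baseSeed = params@seed, replicateCv = 0,
                              condition = "cond") {
  stopifnot(nReplicates >= 1L, nFields >= 1L)
  set.seed(fieldSeed(baseSeed, 0L, 0L))
  repFactor <- exp(stats::rnorm(nReplicates, 0, replicateCv))
  lapply(seq_len(nReplicates), function(r) {
    p <- params
    p@preyAmplitudeAtAnchor <- params@preyAmplitudeAtAnchor * repFactor[r]
    lapply(seq_len(nFields), function(f) {
      simulateField(p, seed = fieldSeed(baseSeed, r, f),
                    meta = list(condition = condition, replicate = r,
                                field = f))
    })
  })
}

## Deterministic footprint statistics of the anchor disk mask:
##   diskArea  : pixels in the disk of radius ceiling(2 * psfSigma),
##   fIn       : expected fraction of a spot's photons inside the disk,
##               averaged over the uniform sub-pixel centre offset,
##   nucDensity: expected per-pixel density of the nucleolar Gaussian over
##               the disk, at the fixed anchor-nucleolus distance.
.footprintStats <- function(params) {
  R <- ceiling(2 * params@psfSigma)
  offs <- diskOffsets(R)
  diskArea <- nrow(offs)
  h <- ceiling(4 * params@psfSigma)
  grid <- seq(-0.5 + 1 / 16, 0.5 - 1 / 16, length.out = 8)
  fIn <- mean(vapply(grid, function(dr) {
    vapply(grid, function(dc) {
      K <- .spotKernel(dr, dc, params@psfSigma, h)
      idx <- cbind(offs$di + h + 1L, offs$dj + h + 1L)
      sum(K[idx])
    }, numeric(1))
  }, numeric(8)))
  d <- .anchorOffsetFrac * params@cellRadius * sqrt(2)
  sn <- .nucSigmaFrac * params@cellRadius
  dens <- exp(-((offs$di - d)^2 + offs$dj^2) / (2 * sn^2)) / (2 * pi * sn^2)
  list(diskArea = diskArea, fIn = fIn, nucDensity = mean(dens))
}

#' Analytic expected recruitment score of a scene
#'
#' Noise-free expectation of the recruitment score measured over the true
#' anchor footprints (disks of radius `ceiling(2 * psfSigma)` around each
#' anchor): the mean green intensity over that region under the generative
#' model, integrating over the sub-pixel spot placement. Used as the recovery
#' target for end-to-end tests; [trueMaskScore()] is its empirical
#' counterpart on a simulated field.
#'
#' @param params a [SceneParams-class] object with `nCells >= 1`.
#' @return expected score (intensity units).
#' @export
expectedScore <- function(params) {
  validObject(params)
  if (params@nCells < 1L)
    stop("expectedScore requires at least one cell")
  st <- .footprintStats(params)
  nRec <- round(params@recruitedFraction * params@nCells)
  params@backgroundMean + params@cellFluor +
    params@nucleolusAmplitude * st$nucDensity +
    (nRec / params@nCells) * params@preyAmplitudeAtAnchor * st$fIn / st$diskArea
}

#' Recruitment score measured with ground-truth anchor masks
#'
#' Mean raw green intensity over the union of true anchor-footprint disks
#' (radius `maskRadius` around each anchor's rounded centre) -- the
#' segmentation-free measurement whose expectation is [expectedScore()].
#'
#' @param field a [FieldImage-class].
#' @param truth the matching [GroundTruth-class].
#' @return numeric score.
#' @export
trueMaskScore <- function(field, truth) {
  an <- truth@anchors
  if (!nrow(an)) stop("no anchors in ground truth")
  g <- field@green
  mask <- matrix(FALSE, nrow(g), ncol(g))
  offs <- diskOffsets(truth@maskRadius)
  for (k in seq_len(nrow(an))) {
    rr <- round(an$row[k]) + offs$di
    cc <- round(an$col[k]) + offs$dj
    ok <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  sum(g[mask]) / sum(mask)
}

#' Simulate a single two-anchor cell for localization testing
#'
#' One cell with two anchoring platforms at a known separation; the prey spot
#' is placed either on the nuclear side (between the anchors) or coincident
#' with one anchor. Used to exercise the inter-anchor profile classifier
#' against ground truth.
#'
#' @param nuclear logical; `TRUE` places the prey between the anchors.
#' @param separationUm anchor separation in micrometres.
#' @param params a [SceneParams-class] (amplitudes, PSF, background, noise).
#' @param seed integer seed.
#' @return list with `field` ([FieldImage-class]), `anchorPoints` (2x2 true
#'   anchor centres), and `nuclear` (the ground-truth flag).
#' @export
simulateTwoAnchorCell <- function(nuclear = TRUE, separationUm = 2,
                                  params = sceneParams(imageShape = c(64L, 64L),
                                                       nCells = 1L),
                                  seed = 1L) {
  set.seed(as.integer(seed))
  nr <- params@imageShape[1]; nc <- params@imageShape[2]
  sepPx <- separationUm / params@pixelSize
  ctr <- c(nr / 2, nc / 2) + stats::runif(2, -1, 1)
  ang <- stats::runif(1, 0, pi)
  u <- c(cos(ang), sin(ang))
  p1 <- ctr - (sepPx / 2) * u + stats::runif(2, -0.3, 0.3)
  p2 <- ctr + (sepPx / 2) * u + stats::runif(2, -0.3, 0.3)
  red <- matrix(0, nr, nc); green <- matrix(0, nr, nc)
  red <- .addSpot(red, p1[1], p1[2], params@psfSigma, params@anchorAmplitude)
  red <- .addSpot(red, p2[1], p2[2], params@psfSigma, params@anchorAmplitude)
  if (nuclear) {
    f <- stats::runif(1, 0.3, 0.7)
    pp <- p1 + f * (p2 - p1)
  } else {
    pp <- if (stats::runif(1) < 0.5) p1 else p2
  }
  green <- .addSpot(green, pp[1], pp[2], params@psfSigma,
                    params@preyAmplitudeAtAnchor)
  bg <- .backgroundField(c(nr, nc), params@backgroundMean,
                         params@backgroundSmoothness)
  red <- red + bg; green <- green + bg
  red <- matrix(pmax(stats::rpois(nr * nc, pmax(red, 0)) +
                       stats::rnorm(nr * nc, 0, params@readNoiseSigma), 0),
                nr, nc)
  green <- matrix(pmax(stats::rpois(nr * nc, pmax(green, 0)) +
                         stats::rnorm(nr * nc, 0, params@readNoiseSigma), 0),
                  nr, nc)
  list(field = new("FieldImage", red = red, green = green,
                   pixelSize = params@pixelSize, meta = list()),
       anchorPoints = rbind(p1, p2), nuclear = nuclear)
}
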