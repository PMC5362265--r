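## Independent brute-force oracles used by the unit and acceptance tests.
## These deliberately share no code with the package internals: index-wise
## loops and closed forms only.

## Symmetric reflection of index i into 1..n (edge pixel repeated).
reflectIdx <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

## Per-pixel disk mean by exhaustive enumeration.
bruteDiskMean <- function(image, radius) {
  nr <- nrow(image); nc <- ncol(image)
  r <- floor(radius)
  out <- matrix(0, nr, nc)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- 0
    for (k in seq_len(nrow(offs))) {
      v <- v + image[reflectIdx(i + offs$di[k], nr),
                     reflectIdx(j + offs$dj[k], nc)]
    }
    out[i, j] <- v / nrow(offs)
  }
  out
}

bruteLocalMeanThreshold <- function(image, radius, offset) {
  image > bruteDiskMean(image, radius) + offset
}

## Grayscale opening (erosion then dilation, disk SE, reflected borders).
bruteErodeDilate <- function(image, radius, op) {
  nr <- nrow(image); nc <- ncol(image)
  r <- floor(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(nrow(offs))
    for (k in seq_len(nrow(offs)))
      vals[k] <- image[reflectIdx(i + offs$di[k], nr),
                       reflectIdx(j + offs$dj[k], nc)]
    out[i, j] <- op(vals)
  }
  out
}

bruteOpening <- function(image, radius)
  bruteErodeDilate(bruteErodeDilate(image, radius, min), radius, max)

## Overlap of two label images by pixel enumeration.
bruteOverlapArea <- function(labA, labB) {
  n <- 0L
  pairs <- character(0)
  for (i in seq_len(nrow(labA))) for (j in seq_len(ncol(labA))) {
    if (labA[i, j] > 0 && labB[i, j] > 0) {
      n <- n + 1L
      pairs <- c(pairs, paste(labA[i, j], labB[i, j]))
    }
  }
  list(area = n, pairs = sort(unique(pairs)))
}

## Recruitment score by pixel enumeration: sum green over (prey & anchor)
## pixels divided by total anchor pixels.
bruteScore <- function(green, preyLab, anchorLab) {
  num <- 0; red <- 0L
  for (i in seq_len(nrow(green))) for (j in seq_len(ncol(green))) {
    if (anchorLab[i, j] > 0) red <- red + 1L
    if (anchorLab[i, j] > 0 && preyLab[i, j] > 0) num <- num + green[i, j]
  }
  num / red
}

## Full 2^(ddCt) ChIP chain with efficiency 1, spreadsheet style: technical
## reps averaged on Ct, quantities 2^(-Ct), then the ratio chain.
ddctOracle <- function(cts, target, control, refLocus, cond, repl) {
  q <- function(locus, frac) {
    sel <- cts$fraction == frac & cts$amplicon == locus &
      cts$condition == cond & cts$replicate == repl
    2^(-mean(cts$ct[sel]))
  }
  rr <- function(locus) q(locus, "IP") / q(locus, "input")
  (rr(target) / rr(control)) / (rr(refLocus) / rr(control))
}

## Optimal perfect matching of 4 points into 2 pairs (exhaustive).
bruteBestPairing <- function(pts) {
  d <- function(a, b) sqrt(sum((pts[a, ] - pts[b, ])^2))
  opts <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
               list(c(1, 4), c(2, 3)))
  costs <- vapply(opts, function(o) d(o[[1]][1], o[[1]][2]) +
                    d(o[[2]][1], o[[2]][2]), numeric(1))
  opts[[which.min(costs)]]
}

## Random small label fixture: a few rectangular blobs.
randomLabels <- function(nr, nc, nBlobs, seed) {
  set.seed(seed)
  lab <- matrix(0L, nr, nc)
  for (b in seq_len(nBlobs)) {
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    i <- sample(seq_len(nr - h), 1); j <- sample(seq_len(nc - w), 1)
    lab[i:(i + h - 1), j:(j + w - 1)] <- b
  }
  lab
}
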