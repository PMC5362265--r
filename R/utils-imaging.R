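## Low-level neighborhood operations on intensity matrices.
##
## Every operation handles image borders by symmetric reflection (the edge
## pixel is repeated: for a 1..n axis the pad reads r..1 | 1..n | n..n-r+1),
## so all downstream segmentation steps share one boundary convention. The
## pad width always equals the kernel radius, which keeps the reflected
## convolution exact for every output pixel.

padReflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("reflection pad radius (", r, ") must be smaller than the image")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

## Integer (di, dj) offsets of a disk of the given radius.
diskOffsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

## Sum of w[k] * image shifted by (di[k], dj[k]), reflection boundary.
shiftWeightedSum <- function(m, di, dj, w) {
  r <- max(abs(c(di, dj)), 1L)
  p <- padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (k in seq_along(di)) {
    out <- out + w[k] *
      p[(r + 1L + di[k]):(r + nr + di[k]),
        (r + 1L + dj[k]):(r + nc + dj[k]), drop = FALSE]
  }
  out
}

#' Mean over a disk neighborhood at every pixel
#'
#' Computes, for each pixel, the mean of the image over the disk of the given
#' radius centred there (integer pixel offsets with `di^2 + dj^2 <= radius^2`),
#' with borders handled by symmetric reflection.
#'
#' @param image numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return numeric matrix of local disk means, same shape as `image`.
#' @export
diskMean <- function(image, radius) {
  stopifnot(is.matrix(image), radius >= 1)
  off <- diskOffsets(radius)
  shiftWeightedSum(image, off$di, off$dj, rep(1 / nrow(off), nrow(off)))
}

#' Gaussian blur with reflected borders
#'
#' Separable Gaussian convolution; the kernel is truncated at 4 sigma and
#' renormalized, borders are reflected.
#'
#' @param image numeric matrix.
#' @param sigma blur standard deviation in pixels (> 0).
#' @return blurred matrix, same shape.
#' @export
gaussBlur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  h <- max(1L, ceiling(4 * sigma))
  ## truncate further if the kernel would not fit the image (reflection pad
  ## must stay smaller than the image)
  h <- min(h, nrow(image) - 1L, ncol(image) - 1L)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(image); nc <- ncol(image)
  ## rows
  p <- padReflect(image, h)
  out <- matrix(0, nr, nc + 2L * h)
  for (i in seq_along(k))
    out <- out + k[i] * p[(i):(i + nr - 1L), , drop = FALSE]
  ## columns (input already row-convolved and row-cropped)
  res <- matrix(0, nr, nc)
  for (j in seq_along(k))
    res <- res + k[j] * out[, (j):(j + nc - 1L), drop = FALSE]
  res
}

## Grayscale erosion / dilation by a disk, reflection boundary.
grayErode <- function(image, radius) {
  off <- diskOffsets(radius)
  r <- max(abs(c(off$di, off$dj)), 1L)
  p <- padReflect(image, r)
  nr <- nrow(image); nc <- ncol(image)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    s <- p[(r + 1L + off$di[k]):(r + nr + off$di[k]),
           (r + 1L + off$dj[k]):(r + nc + off$dj[k]), drop = FALSE]
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

grayDilate <- function(image, radius) {
  off <- diskOffsets(radius)
  r <- max(abs(c(off$di, off$dj)), 1L)
  p <- padReflect(image, r)
  nr <- nrow(image); nc <- ncol(image)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    s <- p[(r + 1L + off$di[k]):(r + nr + off$di[k]),
           (r + 1L + off$dj[k]):(r + nc + off$dj[k]), drop = FALSE]
    out <- if (is.null(out)) s else pmax(out, s)
  }
  out
}

#' Morphological opening by a disk structuring element
#'
#' Erosion followed by dilation with the same disk; anti-extensive
#' (`opening <= image` pointwise) under the reflection boundary.
#'
#' @param image numeric matrix.
#' @param radius disk radius in pixels.
#' @return opened matrix.
#' @export
grayOpening <- function(image, radius) grayDilate(grayErode(image, radius), radius)

#' White top-hat transform
#'
#' `image - opening(image)`: removes structures larger than the disk
#' structuring element, flattening smooth background. Always >= 0.
#'
#' @inheritParams grayOpening
#' @return top-hat matrix, same shape, non-negative.
#' @export
whiteTopHat <- function(image, radius) {
  out <- image - grayOpening(image, radius)
  ## numeric round-off guard; mathematically out >= 0
  out[out < 0] <- 0
  out
}

#' Label 8-connected foreground components
#'
#' Connected components of a binary mask under 8-connectivity, computed on
#' the pixel-adjacency graph. Labels are assigned in order of each
#' component's first pixel in column-major order, so relabeling a label image
#' is idempotent.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of labels (0 = background).
#' @export
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nrow2 <- rows + off[1]; ncol2 <- cols + off[2]
    ok <- nrow2 >= 1L & nrow2 <= nr & ncol2 >= 1L & ncol2 <= nc
    nb <- (ncol2[ok] - 1L) * nr + nrow2[ok]
    hit <- mask[nb]
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok][hit]], id[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[fg] <- match(memb, unique(memb))
  lab
}

## Region table: geometry on the label image, intensities on `raw`.
regionTable <- function(labels, raw) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), area = numeric(),
                      centroidRow = numeric(), centroidCol = numeric(),
                      sumRaw = numeric(), meanRaw = numeric(),
                      maxRow = integer(), maxCol = integer()))
  nr <- nrow(labels)
  lv <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  vals <- raw[idx]
  f <- factor(lv)
  area <- as.numeric(tabulate(f))
  cr <- as.numeric(tapply(rows, f, mean))
  cc <- as.numeric(tapply(cols, f, mean))
  s <- as.numeric(tapply(vals, f, sum))
  ## brightest raw pixel per region (first in column-major order on ties)
  o <- order(lv, -vals, idx)
  first <- o[!duplicated(lv[o])]
  bidx <- idx[first][order(lv[first])]
  data.frame(label = as.integer(levels(f)), area = area,
             centroidRow = cr, centroidCol = cc, sumRaw = s,
             meanRaw = s / area,
             maxRow = ((bidx - 1L) %% nr) + 1L,
             maxCol = ((bidx - 1L) %/% nr) + 1L)
}

## Construct a LabeledSpots object from a label image and raw channel.
newLabeledSpots <- function(labels, raw) {
  new("LabeledSpots", labels = labels, table = regionTable(labels, raw))
}
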