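## Time-course analysis of complex levels: normalization to the maximum
## measurement, inter-measurement assembly/disassembly rates, descriptive
## exponential-decay and logistic fits, and rule-based labeling of the
## three response stages.

#' Construct a time course
#'
#' @param complexId complex label (e.g. `"PolI-Rrn3"`).
#' @param timepoints minutes, strictly increasing.
#' @param levels non-negative detected levels.
#' @return a [TimeCourse-class] object.
#' @export
timeCourse <- function(complexId, timepoints, levels) {
  new("TimeCourse", complexId = complexId, timepoints = as.numeric(timepoints),
      levels = as.numeric(levels), normalized = FALSE)
}

#' Normalize levels to the highest measurement
#'
#' Divides the levels by their maximum so the peak measurement is exactly 1;
#' idempotent.
#'
#' @param tc a [TimeCourse-class].
#' @return normalized [TimeCourse-class].
#' @export
normalizeLevels <- function(tc) {
  m <- max(tc@levels)
  if (m <= 0) stop("cannot normalize an all-zero series")
  new("TimeCourse", complexId = tc@complexId, timepoints = tc@timepoints,
      levels = tc@levels / m, normalized = TRUE)
}

#' Inter-measurement assembly/disassembly rates
#'
#' Forward difference between consecutive measurements:
#' `rate_k = (v[k+1] - v[k]) / (t[k+1] - t[k])`, reported at the interval
#' midpoint. Positive rates are assembly, negative disassembly. The rates
#' telescope exactly: `sum(rate * dt) == v[n] - v[1]`.
#'
#' @param tc a [TimeCourse-class] with >= 2 timepoints.
#' @return a [RateSeries-class].
#' @export
intervalRates <- function(tc) {
  t <- tc@timepoints; v <- tc@levels
  if (length(t) < 2L) stop("need at least two timepoints")
  dt <- diff(t)
  if (any(dt == 0)) stop("duplicate timepoints")
  new("RateSeries", midpoints = (t[-1] + t[-length(t)]) / 2,
      rates = diff(v) / dt, dt = dt)
}

#' Fit an exponential decay to a time course
#'
#' Least-squares fit of `v(t) = offset + amplitude * exp(-t / tau)`
#' (Levenberg-Marquardt). Initialization from the data: `offset ~ v[last]`,
#' `amplitude ~ v[1] - v[last]`, `tau` from a log-linear regression of
#' `v - offset` on `t` over the points where that difference is positive.
#' A constant (or signal-free) series is flagged degenerate; non-convergence
#' is flagged with parameters from the best iterate.
#'
#' @param tc a [TimeCourse-class] with >= 4 points.
#' @return a [KineticFit-class].
#' @export
fitExponentialDecay <- function(tc) {
  t <- tc@timepoints; v <- tc@levels
  stopifnot(length(t) >= 4L)
  off0 <- v[length(v)]
  amp0 <- v[1] - off0
  if (stats::sd(v) < 1e-12 * max(abs(v), 1) ||
      abs(amp0) < 1e-12 * max(abs(v), 1)) {
    return(new("KineticFit", model = "exponential_decay",
               parameters = c(amplitude = 0, tau = NA_real_,
                              offset = mean(v)),
               rss = sum((v - mean(v))^2), converged = TRUE,
               degenerate = TRUE))
  }
  resid0 <- (v - off0) / amp0      # positive, decaying toward 0
  usable <- which(resid0 > 0.02)
  tau0 <- if (length(usable) >= 2L) {
    fitl <- stats::lm(log(resid0[usable]) ~ t[usable])
    sl <- unname(stats::coef(fitl)[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  df <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ offset + amplitude * exp(-t / tau), data = df,
                      start = list(offset = off0, amplitude = amp0,
                                   tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("KineticFit", model = "exponential_decay",
               parameters = c(amplitude = amp0, tau = tau0, offset = off0),
               rss = sum((v - (off0 + amp0 * exp(-t / tau0)))^2),
               converged = FALSE, degenerate = FALSE))
  }
  cf <- stats::coef(fit)
  new("KineticFit", model = "exponential_decay",
      parameters = c(amplitude = cf[["amplitude"]], tau = cf[["tau"]],
                     offset = cf[["offset"]]),
      rss = sum(stats::resid(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE, degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a 4-parameter logistic to a time course
#'
#' Least-squares fit of `v(t) = lo + (hi - lo) / (1 + exp(-s * (t - t50)))`.
#' Initialization: `lo`/`hi` from the data range, `t50` at the point closest
#' to the half-maximum, `s` from a logit-linear regression over interior
#' points. The steepness is unconstrained in sign, so falling sigmoids fit
#' with `s < 0`.
#'
#' @param tc a [TimeCourse-class] with >= 4 points.
#' @return a [KineticFit-class].
#' @export
fitLogistic <- function(tc) {
  t <- tc@timepoints; v <- tc@levels
  stopifnot(length(t) >= 4L)
  lo0 <- min(v); hi0 <- max(v)
  if (hi0 - lo0 < 1e-12 * max(abs(v), 1)) {
    return(new("KineticFit", model = "logistic",
               parameters = c(lo = mean(v), hi = mean(v), t50 = NA_real_,
                              steepness = 0),
               rss = sum((v - mean(v))^2), converged = TRUE,
               degenerate = TRUE))
  }
  mid <- (lo0 + hi0) / 2
  t500 <- t[which.min(abs(v - mid))]
  z <- (v - lo0) / (hi0 - lo0)
  interior <- which(z > 0.05 & z < 0.95)
  s0 <- if (length(interior) >= 2L) {
    fitl <- stats::lm(stats::qlogis(z[interior]) ~ t[interior])
    sl <- unname(stats::coef(fitl)[2])
    if (is.finite(sl) && sl != 0) sl else 4 / diff(range(t))
  } else {
    ## step-like data: sign from the overall trend
    sign(v[length(v)] - v[1]) * 4 / min(diff(t))
  }
  pad <- 0.05 * (hi0 - lo0)
  df <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ lo + (hi - lo) / (1 + exp(-s * (t - t50))),
                      data = df,
                      start = list(lo = lo0 - pad, hi = hi0 + pad,
                                   t50 = t500, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("KineticFit", model = "logistic",
               parameters = c(lo = lo0, hi = hi0, t50 = t500,
                              steepness = s0),
               rss = NA_real_, converged = FALSE, degenerate = FALSE))
  }
  cf <- stats::coef(fit)
  new("KineticFit", model = "logistic",
      parameters = c(lo = cf[["lo"]], hi = cf[["hi"]], t50 = cf[["t50"]],
                     steepness = cf[["s"]]),
      rss = sum(stats::resid(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE, degenerate = FALSE)
}

#' Label the response stages from two rate series
#'
#' Operationalizes the three-stage description of the response: per
#' interval, if both complexes' |rates| fall below `slowThreshold` times the
#' overall maximum |rate| the interval is `consolidation`; otherwise the
#' complex with the larger |rate| labels it (`<idA>_fast` / `<idB>_fast`,
#' ties to the first complex). Contiguous runs are merged and the
#' stage-change boundaries reported.
#'
#' @param ratesA,ratesB [RateSeries-class] on identical interval grids.
#' @param slowThreshold fraction of the maximum |rate| below which both
#'   complexes count as slow (default 0.2).
#' @param idA,idB complex ids used in the stage labels.
#' @return a [StageLabels-class].
#' @export
classifyStages <- function(ratesA, ratesB, slowThreshold = 0.2,
                           idA = "A", idB = "B") {
  if (!isTRUE(all.equal(ratesA@midpoints, ratesB@midpoints)) ||
      !isTRUE(all.equal(ratesA@dt, ratesB@dt)))
    stop("rate series must share the same interval grid")
  a <- ratesA@rates; b <- ratesB@rates
  mx <- max(abs(c(a, b)))
  stage <- ifelse(abs(a) < slowThreshold * mx & abs(b) < slowThreshold * mx,
                  "consolidation",
                  ifelse(abs(a) >= abs(b), paste0(idA, "_fast"),
                         paste0(idB, "_fast")))
  if (mx == 0) stage <- rep("consolidation", length(a))
  starts <- ratesA@midpoints - ratesA@dt / 2
  ends <- ratesA@midpoints + ratesA@dt / 2
  r <- rle(stage)
  ix <- cumsum(r$lengths)
  intervals <- data.frame(
    start = starts[c(1L, utils::head(ix, -1L) + 1L)],
    end = ends[ix], stage = r$values)
  new("StageLabels", intervals = intervals,
      boundaries = intervals$start[-1L])
}
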