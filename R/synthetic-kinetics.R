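## Synthetic kinetic time courses and ChIP-qPCR Ct tables with known truth.

#' Construct kinetic parameters for the synthetic time course
#'
#' Defaults emulate the nutrient-starvation response: the initiation-competent
#' complex (Pol I--Rrn3) decays exponentially with a ~30% drop over the first
#' 15 min and a 60% total reduction (`0.4 + 0.6 exp(-t/10)`), while the
#' inactive homodimer rises sigmoidally, fastest between 15 and 35 min
#' (logistic, t50 = 25 min, steepness 0.2/min).
#'
#' @param rrn3Decay named numeric `c(amplitude, tau, offset)`.
#' @param dimerRise named numeric `c(lo, hi, t50, steepness)`.
#' @param measurementNoiseSd multiplicative noise sd (fraction, default 0.05).
#' @param timepoints sampling times in minutes, strictly increasing.
#' @return a [KineticParams-class] object.
#' @export
kineticParams <- function(rrn3Decay = c(amplitude = 0.6, tau = 10,
                                        offset = 0.4),
                          dimerRise = c(lo = 0, hi = 1, t50 = 25,
                                        steepness = 0.2),
                          measurementNoiseSd = 0.05,
                          timepoints = c(0, 5, 10, 15, 20, 25, 35, 50, 65,
                                         90, 120)) {
  new("KineticParams", rrn3Decay = rrn3Decay, dimerRise = dimerRise,
      measurementNoiseSd = measurementNoiseSd, timepoints = timepoints)
}

## Model curves (noise-free).
.expDecayCurve <- function(t, p) p[["offset"]] + p[["amplitude"]] * exp(-t / p[["tau"]])
.logisticCurve <- function(t, p)
  p[["lo"]] + (p[["hi"]] - p[["lo"]]) /
    (1 + exp(-p[["steepness"]] * (t - p[["t50"]])))

#' Simulate time courses of the two Pol I complexes
#'
#' Evaluates the exponential-decay (Pol I--Rrn3) and logistic (Pol I
#' homodimer) model curves at the configured timepoints, applies
#' multiplicative Gaussian noise with sd `measurementNoiseSd`, and clips at
#' zero.
#'
#' @param kp a [KineticParams-class] object.
#' @param seed integer seed.
#' @return named list of two [TimeCourse-class] objects, `rrn3` and `dimer`.
#' @export
simulateTimecourse <- function(kp, seed = 1L) {
  validObject(kp)
  set.seed(as.integer(seed))
  t <- kp@timepoints
  v1 <- .expDecayCurve(t, kp@rrn3Decay)
  v2 <- .logisticCurve(t, kp@dimerRise)
  if (kp@measurementNoiseSd > 0) {
    v1 <- v1 * (1 + stats::rnorm(length(t), 0, kp@measurementNoiseSd))
    v2 <- v2 * (1 + stats::rnorm(length(t), 0, kp@measurementNoiseSd))
  }
  list(rrn3 = new("TimeCourse", complexId = "PolI-Rrn3", timepoints = t,
                  levels = pmax(v1, 0), normalized = FALSE),
       dimer = new("TimeCourse", complexId = "PolI-dimer", timepoints = t,
                   levels = pmax(v2, 0), normalized = FALSE))
}

#' Simulate a qPCR serial-dilution series
#'
#' Four serial 10-fold dilutions (by default) of a template amplified at the
#' given efficiency: `Ct = intercept + slope * log10(quantity)` with
#' `slope = -1 / log10(1 + efficiency)`, plus Gaussian Ct noise.
#'
#' @param amplicon amplicon name.
#' @param efficiency amplification efficiency in (0, 1.1] (1 = perfect
#'   doubling).
#' @param intercept Ct at relative quantity 1.
#' @param nDilutions number of 10-fold dilution points (default 4).
#' @param nTech technical replicates per point (default 3).
#' @param ctNoiseSd Ct noise sd in cycles (default 0.15; 0 = noise-free).
#' @param seed integer seed.
#' @return data.frame with columns `amplicon`, `log10Quantity`, `techRep`,
#'   `ct`.
#' @export
simulateDilutionSeries <- function(amplicon = "35S", efficiency = 1,
                                   intercept = 20, nDilutions = 4L,
                                   nTech = 3L, ctNoiseSd = 0.15, seed = 1L) {
  set.seed(as.integer(seed))
  lq <- -(seq_len(nDilutions) - 1)
  slope <- -1 / log10(1 + efficiency)
  out <- expand.grid(techRep = seq_len(nTech), log10Quantity = lq)
  out$ct <- intercept + slope * out$log10Quantity +
    stats::rnorm(nrow(out), 0, ctNoiseSd)
  data.frame(amplicon = amplicon, log10Quantity = out$log10Quantity,
             techRep = out$techRep, ct = out$ct)
}

#' Simulate a ChIP-qPCR Ct table with known occupancies
#'
#' Generates a long-format Ct table (IP and input fractions, several loci,
#' conditions and biological replicates, technical triplicates) from known
#' ground-truth occupancies. The IP quantity at a locus is
#' `pulldown * occupancy(condition, locus) * input quantity`; Cts follow the
#' standard-curve model at the given efficiency with Gaussian Ct noise.
#'
#' @param occupancy data.frame with columns `condition`, `locus`, `occ` (true
#'   relative occupancy; the control locus should have `occ = 1`).
#' @param efficiency amplification efficiency (default 1).
#' @param intercept Ct at relative quantity 1 (default 20).
#' @param pulldown global IP recovery factor (default 0.05).
#' @param nBio biological replicates (default 3).
#' @param nTech technical replicates (default 3).
#' @param bioCv log-normal CV of the replicate effect on occupancy.
#' @param ctNoiseSd Ct noise sd in cycles (default 0.15).
#' @param seed integer seed.
#' @return data.frame in the `CtTable` layout: `sample`, `fraction`,
#'   `amplicon`, `condition`, `replicate`, `techRep`, `ct`.
#' @export
simulateCtTable <- function(occupancy, efficiency = 1, intercept = 20,
                            pulldown = 0.05, nBio = 3L, nTech = 3L,
                            bioCv = 0.1, ctNoiseSd = 0.15, seed = 1L) {
  stopifnot(all(c("condition", "locus", "occ") %in% names(occupancy)))
  set.seed(as.integer(seed))
  slope <- -1 / log10(1 + efficiency)
  rows <- list()
  for (i in seq_len(nrow(occupancy))) {
    cond <- occupancy$condition[i]; locus <- occupancy$locus[i]
    for (b in seq_len(nBio)) {
      bioF <- exp(stats::rnorm(1, 0, bioCv))
      qInput <- 1
      qIP <- pulldown * occupancy$occ[i] * bioF * qInput
      for (frac in c("IP", "input")) {
        q <- if (frac == "IP") qIP else qInput
        ct0 <- intercept + slope * log10(q)
        for (tr in seq_len(nTech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = paste(cond, b, sep = "_"), fraction = frac,
            amplicon = locus, condition = cond, replicate = b,
            techRep = tr, ct = ct0 + stats::rnorm(1, 0, ctNoiseSd))
        }
      }
    }
  }
  do.call(rbind, rows)
}
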