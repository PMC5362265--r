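## ChIP-qPCR quantification chain: standard curves from serial dilutions,
## Ct -> relative quantity, IP/input normalization, division by a
## non-transcribed control region, and relative occupancy vs the reference
## locus (5S) and a reference condition.

#' Fit a qPCR standard curve from a serial dilution
#'
#' Ordinary least-squares line of mean Ct (over technical replicates) versus
#' log10 relative quantity. Efficiency is `10^(-1/slope) - 1`; perfect
#' doubling (Ct drops ~3.3219 per 10-fold dilution) gives efficiency 1.
#'
#' @param dilutionCts data.frame with columns `log10Quantity` and `ct`
#'   (optionally `amplicon`; replicate rows per dilution are averaged).
#' @param amplicon amplicon name recorded in the result (default from the
#'   table if present).
#' @return a [StdCurve-class] object.
#' @export
fitStandardCurve <- function(dilutionCts, amplicon = NULL) {
  stopifnot(all(c("log10Quantity", "ct") %in% names(dilutionCts)))
  if (is.null(amplicon))
    amplicon <- if ("amplicon" %in% names(dilutionCts))
      as.character(dilutionCts$amplicon[1]) else "amplicon"
  mct <- stats::aggregate(ct ~ log10Quantity, data = dilutionCts, FUN = mean)
  if (nrow(mct) < 3L) stop("need >= 3 distinct dilutions")
  fit <- stats::lm(ct ~ log10Quantity, data = mct)
  slope <- stats::coef(fit)[["log10Quantity"]]
  if (slope >= 0)
    stop("invalid standard curve: slope must be negative (higher dilution, ",
         "higher Ct)")
  tss <- sum((mct$ct - mean(mct$ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  new("StdCurve", amplicon = amplicon, slope = slope,
      intercept = stats::coef(fit)[["(Intercept)"]],
      efficiency = 10^(-1 / slope) - 1, r2 = r2)
}

#' Relative quantity from a Ct value
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept) / slope)`.
#' With the slope negative, a higher Ct gives a lower quantity.
#'
#' @param ct Ct value(s).
#' @param curve a [StdCurve-class].
#' @return relative quantity (same length as `ct`).
#' @export
quantifyCt <- function(ct, curve) {
  validObject(curve)
  10^((ct - curve@intercept) / curve@slope)
}

#' Relative occupancy from a ChIP-qPCR Ct table
#'
#' Per condition and biological replicate: technical replicates are averaged
#' on the Ct scale (geometric mean on the quantity scale); Cts are converted
#' to quantities through each amplicon's standard curve; then
#' `r(locus) = Q_IP / Q_input`, `c(locus) = r(locus) / r(control)`,
#' `occupancy = c(target) / c(reference locus)`. Biological replicates are
#' summarized as mean +/- SD, and fold changes are reported relative to the
#' reference condition (whose fold is 1 by construction). Since every step
#' is a ratio, the result is invariant to adding a constant to all Cts.
#'
#' @param cts data.frame with columns `fraction` (`"IP"`/`"input"`),
#'   `amplicon`, `condition`, `replicate`, `ct` (and optionally `techRep`).
#' @param curves named list of [StdCurve-class], one per amplicon used.
#' @param target target locus (e.g. the 35S promoter amplicon).
#' @param control non-transcribed control region (default `"chrVII"`).
#' @param referenceLocus reference gene (default `"5S"`).
#' @param referenceCondition condition whose occupancy defines fold 1.
#' @return an [OccupancyResult-class] object.
#' @export
relativeOccupancy <- function(cts, curves, target, control = "chrVII",
                              referenceLocus = "5S",
                              referenceCondition) {
  need <- c("fraction", "amplicon", "condition", "replicate", "ct")
  if (!all(need %in% names(cts)))
    stop("Ct table lacks column(s): ",
         paste(setdiff(need, names(cts)), collapse = ", "))
  loci <- c(target, control, referenceLocus)
  missingLoci <- setdiff(loci, unique(as.character(cts$amplicon)))
  if (length(missingLoci))
    stop("Ct table lacks required locus/loci: ",
         paste(missingLoci, collapse = ", "))
  if (!all(loci %in% names(curves)))
    stop("missing standard curve(s) for: ",
         paste(setdiff(loci, names(curves)), collapse = ", "))
  if (!referenceCondition %in% cts$condition)
    stop("reference condition '", referenceCondition, "' absent from table")
  sub <- cts[cts$amplicon %in% loci, , drop = FALSE]
  ## technical replicates: average on the Ct scale
  agg <- stats::aggregate(ct ~ fraction + amplicon + condition + replicate,
                          data = sub, FUN = mean)
  ## per (condition, replicate): the full ratio chain
  combos <- unique(agg[, c("condition", "replicate")])
  occ <- vapply(seq_len(nrow(combos)), function(i) {
    cnd <- combos$condition[i]; rep_ <- combos$replicate[i]
    q <- function(locus, frac) {
      row <- agg$fraction == frac & agg$amplicon == locus &
        agg$condition == cnd & agg$replicate == rep_
      if (sum(row) != 1L)
        stop("missing Ct for condition '", cnd, "', replicate ", rep_,
             ", locus '", locus, "', fraction '", frac, "'")
      quantifyCt(agg$ct[row], curves[[locus]])
    }
    r <- function(locus) q(locus, "IP") / q(locus, "input")
    cNorm <- function(locus) r(locus) / r(control)
    cNorm(target) / cNorm(referenceLocus)
  }, numeric(1))
  if (any(!is.finite(occ)) || any(occ <= 0))
    stop("non-positive or non-finite occupancy; check Ct values")
  per <- data.frame(condition = combos$condition,
                    replicate = combos$replicate, occupancy = occ)
  sm <- do.call(rbind, lapply(split(per, per$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$occupancy),
               sd = if (nrow(d) > 1) stats::sd(d$occupancy) else NA_real_,
               n = nrow(d))))
  refMean <- sm$mean[sm$condition == referenceCondition]
  sm$fold <- sm$mean / refMean
  rownames(sm) <- NULL
  new("OccupancyResult", perReplicate = per, summary = sm, target = target,
      control = control, referenceLocus = referenceLocus,
      referenceCondition = referenceCondition)
}
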