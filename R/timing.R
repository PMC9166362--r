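## Occupied-bin view of a curve, warning when interpolation will have
## to bridge empty interior bins.
occupiedBins <- function(curve, warnGaps = TRUE) {
  occ <- which(!is.na(curve@mean))
  if (warnGaps && length(occ) > 1 &&
      any(diff(curve@binCenters[occ]) > 1.5 * curve@binWidth))
    warning("empty age bins inside the curve; timing estimates ",
            "interpolate across them")
  list(center = curve@binCenters[occ], mean = curve@mean[occ])
}

#' Arrival time t0 of a protein at midcell
#'
#' t0 is the division-cycle age at which more fluorescence first sits
#' at midcell than in the rest of the cell, i.e. where the age-binned
#' mean FCPlus first turns positive. The estimate is the smallest age
#' at which the binned mean crosses above zero and stays above it for
#' at least `persistence` consecutive occupied bins; the crossing age
#' is linearly interpolated between the last non-positive and first
#' positive bin centers. If the first occupied bin is already positive,
#' t0 = 0.
#'
#' "Positive" means exceeding `tolRel * max(|mean|)` rather than 0
#' exactly. A strict sign test has unbounded sensitivity: on clean
#' data, the bin just below the true onset picks up a sub-percent
#' positive mean purely from length-rank age assignment scatter (cells
#' barely past the onset ranked one bin early), and machine rounding
#' alone can flip exact-zero bins positive. The default detection
#' floor of 1% of the curve maximum makes the estimator's sensitivity
#' explicit while staying far below any biologically meaningful
#' surplus; set `tolRel = 0` for the strict sign rule.
#'
#' @param curve A [BinnedCurve-class] of FCPlus values with >= 4
#'   occupied bins.
#' @param persistence Consecutive positive bins required (default 2).
#' @param tolRel Onset detection floor relative to the curve maximum
#'   (default 0.01).
#' @return t0, an age fraction in `[0, 1]`.
#' @section Errors: a curve that never turns positive raises a
#'   condition of class `noOnsetError` ("no midcell localization").
#' @seealso [estimateThalf()], [estimateTiming()]
#' @export
estimateT0 <- function(curve, persistence = 2, tolRel = 0.01) {
  stopifnot(is(curve, "BinnedCurve"))
  ob <- occupiedBins(curve)
  if (length(ob$mean) < 4)
    stop("need at least 4 occupied bins to estimate t0")
  thr <- tolRel * max(abs(ob$mean))
  pos <- ob$mean > thr
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= persistence)
  if (!length(hit))
    stop(errorCondition(
      "no onset: binned FCPlus never stays positive (no midcell localization)",
      class = c("noOnsetError", "error", "condition")))
  i1 <- starts[hit[1]]
  if (i1 == 1L) return(0)
  i0 <- i1 - 1L
  ob$center[i0] + (ob$center[i1] - ob$center[i0]) *
    (thr - ob$mean[i0]) / (ob$mean[i1] - ob$mean[i0])
}

#' Half-maximum arrival time t1/2 and curve maximum
#'
#' The maximum of the binned FCPlus means (the curve usually reaches a
#' plateau before declining late in the cycle, which makes the maximum
#' itself a poor timing marker) is halved, and t1/2 is the first age,
#' ascending, at which the curve reaches that half-maximum, linearly
#' interpolated between the bracketing bin centers.
#'
#' @param curve A [BinnedCurve-class] of FCPlus values; [estimateT0()]
#'   must succeed on it.
#' @param persistence,tolRel Passed to the internal [estimateT0()]
#'   check.
#' @return A list with `t_half` (age fraction) and `fc_max`
#'   (fluorescence units).
#' @export
estimateThalf <- function(curve, persistence = 2, tolRel = 0.01) {
  stopifnot(is(curve, "BinnedCurve"))
  estimateT0(curve, persistence, tolRel)  # errors if no onset
  ob <- occupiedBins(curve, warnGaps = FALSE)
  iMax <- which.max(ob$mean)
  fcMax <- ob$mean[iMax]
  if (iMax == 1L)
    warning("pathological curve shape: maximum at the first occupied ",
            "bin")
  half <- fcMax / 2
  i1 <- which(ob$mean >= half)[1]
  if (i1 == 1L) return(list(t_half = ob$center[1], fc_max = fcMax))
  i0 <- i1 - 1L
  tHalf <- ob$center[i0] + (ob$center[i1] - ob$center[i0]) *
    (half - ob$mean[i0]) / (ob$mean[i1] - ob$mean[i0])
  list(t_half = tHalf, fc_max = fcMax)
}

#' One-replicate timing summary
#'
#' Runs the full per-replicate pipeline -- FCPlus per cell, length-rank
#' age assignment, age binning, t0 and t1/2 estimation -- and returns
#' one row of timing results.
#'
#' @param pop A [CellPopulation-class].
#' @param protein Label for the protein that was immunolabeled.
#' @param midcellWidth,binWidth,ciLevel Analysis parameters (defaults
#'   0.8 um, 5% bins, 95%).
#' @param persistence,tolRel See [estimateT0()].
#' @return A one-row `data.frame`: `protein`, `strain`,
#'   `replicate_id`, `t0`, `t_half`, `fc_max`, `n_cells`.
#' @export
estimateTiming <- function(pop, protein = "protein",
                           midcellWidth = 0.8, binWidth = 0.05,
                           ciLevel = 0.95, persistence = 2,
                           tolRel = 0.01) {
  stopifnot(is(pop, "CellPopulation"))
  fc <- fcplus(pop, midcellWidth)
  ages <- assignAges(fc$length_um)$age
  curve <- binByAge(fc$fcplus, ages, binWidth, ciLevel)
  t0 <- estimateT0(curve, persistence, tolRel)
  th <- estimateThalf(curve, persistence, tolRel)
  data.frame(protein = protein, strain = strain(pop),
             replicate_id = replicateId(pop), t0 = t0,
             t_half = th$t_half, fc_max = th$fc_max,
             n_cells = nrow(fc))
}

#' Compare arrival timing between two strains
#'
#' Unpaired two-sided Welch t-test on per-replicate t0 or t1/2 values
#' of a parental versus a mutant strain. The mean difference is
#' reported as parental minus mutant, both as an age fraction and in
#' percent of the division cycle. Significance stars follow the
#' convention `***` for p <= 0.0001, `**` for p <= 0.001, `*` for
#' p <= 0.05, `ns` otherwise.
#'
#' @param parental,mutant `data.frame`s of per-replicate timing results
#'   as returned by [estimateTiming()] (>= 2 replicates each).
#' @param statistic `"t0"` or `"t_half"`.
#' @return A one-row `data.frame`: `statistic_name`,
#'   `mean_difference`, `mean_difference_pct`, `p_value`,
#'   `n_parental`, `n_mutant`, `significance`.
#' @export
compareStrains <- function(parental, mutant,
                           statistic = c("t0", "t_half")) {
  statistic <- match.arg(statistic)
  x <- parental[[statistic]]
  y <- mutant[[statistic]]
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient replicates: need >= 2 per strain")
  diffMean <- mean(x) - mean(y)
  p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    ## degenerate: both strains constant; t.test would error
    if (mean(x) == mean(y)) 1 else 0
  } else {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  stars <- if (p <= 1e-4) "***" else if (p <= 1e-3) "**" else
    if (p <= 0.05) "*" else "ns"
  data.frame(statistic_name = statistic, mean_difference = diffMean,
             mean_difference_pct = 100 * diffMean, p_value = p,
             n_parental = length(x), n_mutant = length(y),
             significance = stars)
}
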