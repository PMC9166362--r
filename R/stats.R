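#' Assign cell-division-cycle ages from length rank
#'
#' In a steady-state population, a cell's position in the division
#' cycle can be inferred from its length rank: with cells sorted
#' ascending by length and 0-based rank `r` among `n` cells,
#' `age = ln(1 - 0.5 * r / (n - 1)) / ln(0.5)`, which inverts the
#' steady-state age CDF `F(a) = 2 (1 - 2^(-a))`. The shortest cell gets
#' age 0 and the longest exactly age 1 (kept; the last age bin is
#' closed). Ties in length keep their input order (stable sort), each
#' tied cell retaining its own integer rank, so ages stay monotone.
#'
#' @param lengths Cell lengths, um, all > 0; at least 2 cells.
#' @return A `data.frame` with `rank` (0-based, ascending length) and
#'   `age` in `[0, 1]`, in input order.
#' @examples
#' assignAges(c(2, 2.5, 3))$age   # 0, 0.41504, 1
#' @export
assignAges <- function(lengths) {
  n <- length(lengths)
  if (n < 2) stop("insufficient data: need at least 2 cells")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths must be finite and > 0")
  rank0 <- integer(n)
  rank0[order(lengths)] <- seq_len(n) - 1L   # stable: ties keep order
  data.frame(rank = rank0,
             age = log(1 - 0.5 * rank0 / (n - 1)) / log(0.5))
}

#' Sphero-cylinder cell volume
#'
#' Volume of a rod modeled as a cylinder with hemispherical caps:
#' `pi r^2 (L - 2 r) + (4/3) pi r^3` with `r = diameter / 2`. At
#' `L = diameter` this degenerates to a sphere.
#'
#' @param length,diameter um; `length >= diameter > 0`. Vectorized.
#' @return Volume in um^3.
#' @examples
#' cellVolume(3, 1)   # 2.0944
#' @export
cellVolume <- function(length, diameter) {
  if (any(diameter <= 0) || any(length < diameter))
    stop("geometry error: need length >= diameter > 0")
  r <- diameter / 2
  pi * r^2 * (length - 2 * r) + (4 / 3) * pi * r^3
}

## Per-sample overlap (in samples, i.e. 0..1 each) of a profile's
## pixel-wide slabs with the central axial window of `window` um.
## Fractional edge pixels are weighted linearly; sum(weights) equals
## window * pitch when the window fits inside the profile.
windowWeights <- function(nSamples, pitch, window = 0.8) {
  dx <- 1 / pitch
  lo <- (nSamples * dx - window) / 2
  hi <- (nSamples * dx + window) / 2
  left <- (seq_len(nSamples) - 1) * dx
  pmax(pmin(left + dx, hi) - pmax(left, lo), 0) / dx
}

fcplusCore <- function(profile, lengthUm, diameter, pitch,
                       midcellWidth) {
  fMid <- sum(profile * windowWeights(length(profile), pitch,
                                      midcellWidth))
  totalF <- sum(profile)
  r <- diameter / 2
  vMid <- pi * r^2 * midcellWidth
  vRest <- cellVolume(lengthUm, diameter) - vMid
  cMid <- fMid / vMid
  cRest <- (totalF - fMid) / vRest
  c(F_mid = fMid, F_rest = totalF - fMid, V_mid = vMid,
    V_rest = vRest, C_mid = cMid, C_rest = cRest,
    fcplus = (cMid - cRest) * vMid, total_F = totalF)
}

#' FCPlus: the midcell fluorescence surplus
#'
#' For each cell, the axial profile is split into the central
#' `midcellWidth` um window (default 0.8 um) and the remainder.
#' Fluorescence is integrated over each part (fractional edge pixels
#' weighted linearly), divided by the corresponding volume -- the
#' window is a pure cylindrical slab `V_mid = pi r^2 w`, the remainder
#' the rest of the sphero-cylinder -- and the concentration difference
#' is multiplied by the midcell volume:
#' `FCPlus = (C_mid - C_rest) * V_mid`. A volume-uniform signal gives
#' 0; a signal entirely inside the window gives the total fluorescence.
#'
#' The cylindrical-slab treatment of the window requires
#' `length > midcellWidth + diameter`; shorter cells are excluded and
#' counted in a message (the number excluded is also attached as
#' attribute `n_excluded`).
#'
#' @param pop A [CellPopulation-class].
#' @param midcellWidth Axial window width, um (default 0.8).
#' @return A `data.frame`, one row per retained cell: `cell_id`,
#'   `length_um`, `diameter_um`, `F_mid`, `F_rest`, `V_mid`, `V_rest`,
#'   `C_mid`, `C_rest`, `fcplus`, `total_F`.
#' @seealso [fcplusFromParts()] for precomputed integrals,
#'   [binByAge()] to build the age curve.
#' @export
setGeneric("fcplus", function(pop, midcellWidth = 0.8)
  standardGeneric("fcplus"))

#' @rdname fcplus
#' @export
setMethod("fcplus", "CellPopulation", function(pop, midcellWidth = 0.8) {
  len <- cellLengths(pop)
  dia <- cellDiameters(pop)
  keep <- len > midcellWidth + dia
  if (any(!keep))
    message("fcplus: excluded ", sum(!keep),
            " cell(s) too short for a cylindrical midcell window")
  if (!any(keep)) stop("no cells long enough for the midcell window")
  profs <- as.list(profiles(pop))
  rows <- t(vapply(which(keep), function(i)
    fcplusCore(profs[[i]], len[i], dia[i], pixelPitch(pop),
               midcellWidth),
    numeric(8)))
  out <- data.frame(cell_id = cellIds(pop)[keep],
                    length_um = len[keep], diameter_um = dia[keep],
                    rows)
  attr(out, "n_excluded") <- sum(!keep)
  out
})

#' FCPlus from precomputed integrated fluorescence
#'
#' Same statistic as [fcplus()] but starting from already-integrated
#' midcell and rest fluorescence rather than a profile.
#'
#' @param fMid,fRest Integrated fluorescence inside / outside the
#'   central window.
#' @param length,diameter Cell dimensions, um.
#' @param midcellWidth Window width, um.
#' @return Named vector as one row of [fcplus()] output (from `F_mid`
#'   to `total_F`).
#' @examples
#' fcplusFromParts(60, 40, 3, 1)[["fcplus"]]   # 42.86
#' @export
fcplusFromParts <- function(fMid, fRest, length, diameter,
                            midcellWidth = 0.8) {
  if (length <= midcellWidth + diameter)
    stop("short-cell error: length must exceed midcellWidth + diameter")
  r <- diameter / 2
  vMid <- pi * r^2 * midcellWidth
  vRest <- cellVolume(length, diameter) - vMid
  cMid <- fMid / vMid
  cRest <- fRest / vRest
  c(F_mid = fMid, F_rest = fRest, V_mid = vMid, V_rest = vRest,
    C_mid = cMid, C_rest = cRest, fcplus = (cMid - cRest) * vMid,
    total_F = fMid + fRest)
}

#' Bin per-cell values into division-cycle age classes
#'
#' Averages a per-cell quantity (FCPlus, concentration, ...) in fixed
#' age classes (default 5%) and attaches a two-sided Student-t
#' confidence half-width per bin (default 95%); `qt(0.975, n-1) * s /
#' sqrt(n)`, 0 for singleton bins. Bins partition `[0, 1]`; the last
#' bin is closed so the longest cell (age exactly 1) is kept. Empty
#' bins carry `NA`, never 0. Counts always sum to the number of input
#' cells.
#'
#' @param values Per-cell values.
#' @param ages Matching ages in `[0, 1]`.
#' @param binWidth Age-class width (default 0.05).
#' @param ciLevel Confidence level (default 0.95).
#' @param valueKind One of `"fcplus"`, `"concentration"`,
#'   `"molecules"`, `"normalized"`.
#' @return A [BinnedCurve-class].
#' @export
binByAge <- function(values, ages, binWidth = 0.05, ciLevel = 0.95,
                     valueKind = "fcplus") {
  if (length(values) != length(ages))
    stop("values and ages must have the same length")
  if (any(ages < 0 | ages > 1)) stop("ages must be in [0, 1]")
  nBins <- as.integer(ceiling(1 / binWidth - 1e-9))
  bin <- pmin(floor(ages / binWidth), nBins - 1L) + 1L
  count <- tabulate(bin, nbins = nBins)
  mu <- rep(NA_real_, nBins)
  ci <- rep(NA_real_, nBins)
  for (b in which(count > 0L)) {
    v <- values[bin == b]
    mu[b] <- mean(v)
    ci[b] <- if (length(v) > 1)
      stats::qt((1 + ciLevel) / 2, length(v) - 1) *
        stats::sd(v) / sqrt(length(v)) else 0
  }
  new("BinnedCurve",
      binCenters = (seq_len(nBins) - 0.5) * binWidth,
      mean = mu, ciHalfwidth = ci, count = as.integer(count),
      valueKind = valueKind, binWidth = binWidth, ciLevel = ciLevel)
}

#' Min-max normalize a binned curve
#'
#' Maps the occupied-bin means affinely so the minimum becomes 0 and
#' the maximum 1; CI half-widths are scaled by the same factor. Used to
#' put proteins with different molecule numbers and antibody affinities
#' on a common timing scale before comparing or averaging curves.
#'
#' @param curve A [BinnedCurve-class] with at least 2 occupied bins of
#'   distinct means.
#' @return A [BinnedCurve-class] with `valueKind = "normalized"`.
#' @export
minmaxNormalize <- function(curve) {
  stopifnot(is(curve, "BinnedCurve"))
  occ <- !is.na(curve@mean)
  if (sum(occ) < 2 || diff(range(curve@mean[occ])) == 0)
    stop("degenerate normalization: need >= 2 occupied bins with ",
         "distinct means")
  lo <- min(curve@mean[occ])
  hi <- max(curve@mean[occ])
  initialize(curve, mean = (curve@mean - lo) / (hi - lo),
             ciHalfwidth = curve@ciHalfwidth / (hi - lo),
             valueKind = "normalized")
}

#' Average binned curves across replicates
#'
#' Per-bin unweighted mean over the replicates that possess the bin;
#' the confidence half-width reflects between-replicate variation
#' (Student-t on the replicate means; 0 where only one replicate
#' contributes). The `count` slot of the result holds the number of
#' replicates contributing per bin.
#'
#' @param curves List of >= 2 [BinnedCurve-class] objects on identical
#'   bin grids with the same `valueKind`.
#' @param ciLevel Confidence level for the between-replicate interval.
#' @return A [BinnedCurve-class].
#' @export
averageReplicates <- function(curves, ciLevel = 0.95) {
  if (!is.list(curves) || length(curves) < 2)
    stop("need a list of at least 2 curves")
  ref <- curves[[1]]
  for (cv in curves[-1]) {
    if (!isTRUE(all.equal(cv@binCenters, ref@binCenters)) ||
        cv@binWidth != ref@binWidth)
      stop("mismatched bin grids")
    if (cv@valueKind != ref@valueKind)
      stop("mismatched valueKind across replicates")
  }
  m <- vapply(curves, function(cv) cv@mean,
              numeric(length(ref@binCenters)))
  k <- rowSums(!is.na(m))
  mu <- ifelse(k > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  ci <- rep(NA_real_, length(k))
  ci[k == 1] <- 0
  many <- which(k > 1)
  for (b in many) {
    v <- m[b, !is.na(m[b, ])]
    ci[b] <- stats::qt((1 + ciLevel) / 2, length(v) - 1) *
      stats::sd(v) / sqrt(length(v))
  }
  new("BinnedCurve", binCenters = ref@binCenters, mean = mu,
      ciHalfwidth = ci, count = as.integer(k),
      valueKind = ref@valueKind, binWidth = ref@binWidth,
      ciLevel = ciLevel)
}

#' Convert an FCPlus curve to molecules at midcell
#'
#' Scales binned FCPlus linearly into molecule numbers using an
#' external per-cell copy-number calibration: `molecules = nTotal *
#' fcplus / meanTotalF`, where `meanTotalF` is the population mean
#' total fluorescence per cell (the culture average, matching the
#' calibration count, which is itself a culture average; 133
#' molecules/cell for the protein this analysis was developed for).
#'
#' @param curve A [BinnedCurve-class] of FCPlus values.
#' @param meanTotalF Mean total fluorescence per average cell (> 0).
#' @param nTotal Calibrated molecules per average cell (default 133).
#' @return A [BinnedCurve-class] with `valueKind = "molecules"`.
#' @export
moleculesAtMidcell <- function(curve, meanTotalF, nTotal = 133) {
  stopifnot(is(curve, "BinnedCurve"))
  if (length(meanTotalF) != 1L || !is.finite(meanTotalF) ||
      meanTotalF <= 0)
    stop("meanTotalF must be a single positive number")
  if (nTotal <= 0) stop("nTotal must be > 0")
  f <- nTotal / meanTotalF
  initialize(curve, mean = curve@mean * f,
             ciHalfwidth = curve@ciHalfwidth * f,
             valueKind = "molecules")
}

#' Midcell fluorescence surplus per um of cell circumference
#'
#' `fcplus / (pi * diameter)`: normalizes the midcell surplus by the
#' circumference of the division site, for comparing strains of
#' different width.
#'
#' @param fcplusValues FCPlus values (vectorized).
#' @param diameter Cell diameters, um (> 0).
#' @return Fluorescence per um.
#' @export
midcellDensityPerCircumference <- function(fcplusValues, diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  fcplusValues / (pi * diameter)
}

#' Total fluorescence concentration per cell volume
#'
#' Per-cell total profile fluorescence divided by the sphero-cylinder
#' cell volume, in fluorescence units per um^3.
#'
#' @param pop A [CellPopulation-class].
#' @return Numeric vector, one value per cell.
#' @export
concentrationPerVolume <- function(pop) {
  stopifnot(is(pop, "CellPopulation"))
  tot <- vapply(as.list(profiles(pop)), sum, 0)
  tot / cellVolume(cellLengths(pop), cellDiameters(pop))
}
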