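#' @rdname GrowthLaw-class
#' @param birthLength Length at birth, um.
#' @param mode Growth mode, `"exponential"` (default) or `"linear"`.
#' @param diameter Cell diameter, um.
#' @export
GrowthLaw <- function(birthLength = 2.0,
                      mode = c("exponential", "linear"),
                      diameter = 0.9) {
  new("GrowthLaw", birthLength = birthLength,
      mode = match.arg(mode), diameter = diameter)
}

#' @rdname RecruitmentModel-class
#' @param t0True,riseWidth,plateauFraction,declineAge,riseShape See the
#'   class slots.
#' @param expressionLaw,meanMolecules,ringSigma,noiseCv,countingNoise,photonGain
#'   See the class slots.
#' @export
RecruitmentModel <- function(t0True = 0.25, riseWidth = 0.2,
                             plateauFraction = 0.6, declineAge = NA_real_,
                             riseShape = c("linear", "smoothstep"),
                             expressionLaw = c("volume", "constant"),
                             meanMolecules = 133, ringSigma = 0.1,
                             noiseCv = 0.1, countingNoise = FALSE,
                             photonGain = 100) {
  new("RecruitmentModel", t0True = t0True, riseWidth = riseWidth,
      plateauFraction = plateauFraction,
      declineAge = as.numeric(declineAge),
      riseShape = match.arg(riseShape),
      expressionLaw = match.arg(expressionLaw),
      meanMolecules = meanMolecules, ringSigma = ringSigma,
      noiseCv = noiseCv, countingNoise = countingNoise,
      photonGain = photonGain)
}

#' Sample steady-state division-cycle ages
#'
#' In a steadily growing (balanced exponential) culture the density of
#' cell ages is `f(a) = 2^(1-a) * ln 2` on `[0, 1)`: newborn cells are
#' twice as frequent as dividing ones. Ages are drawn by inverting the
#' CDF `F(a) = 2 (1 - 2^(-a))`, i.e. `age = ln(1 - u/2) / ln(1/2)` with
#' `u` uniform on `[0, 1)` -- the same transformation that maps a length
#' rank to an age in [assignAges()].
#'
#' @param n Number of ages to draw (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` ages in `[0, 1)`.
#' @examples
#' mean(sampleAges(1e5, seed = 1))   # ~ 1/ln(2) - 1 = 0.4427
#' @export
sampleAges <- function(n, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a single integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  log(1 - 0.5 * u) / log(0.5)
}

#' Cell length at a given division-cycle age
#'
#' @param age Ages in `[0, 1)` (age 1 is the instant of division).
#' @param law A [GrowthLaw-class].
#' @return Lengths in um; strictly increasing in age, doubling the
#'   birth length over one full cycle in either mode.
#' @examples
#' lengthFromAge(0.5, GrowthLaw(birthLength = 2))   # 2 * sqrt(2)
#' @export
lengthFromAge <- function(age, law) {
  stopifnot(is(law, "GrowthLaw"))
  if (any(age < 0 | age >= 1))
    stop("age must be in [0, 1)")
  switch(law@mode,
         exponential = law@birthLength * 2^age,
         linear = law@birthLength * (1 + age))
}

#' Fraction of cellular molecules at midcell at a given age
#'
#' Implements the recruitment time course of a [RecruitmentModel-class]:
#' 0 before the onset age, a continuous rise to the plateau over
#' `riseWidth`, constant plateau, and an optional linear decline to 0
#' between `declineAge` and division. `t0True = 1` encodes a protein
#' that never recruits.
#'
#' @param age Ages in `[0, 1]`.
#' @param model A [RecruitmentModel-class].
#' @return Midcell fractions in `[0, plateauFraction]`, continuous in
#'   age.
#' @export
midcellFraction <- function(age, model) {
  stopifnot(is(model, "RecruitmentModel"))
  if (any(age < 0 | age > 1)) stop("age must be in [0, 1]")
  if (model@t0True >= 1) return(rep(0, length(age)))
  s <- pmin(pmax((age - model@t0True) / model@riseWidth, 0), 1)
  if (model@riseShape == "smoothstep") s <- s * s * (3 - 2 * s)
  f <- model@plateauFraction * s
  if (!is.na(model@declineAge)) {
    span <- 1 - model@declineAge
    dec <- if (span > 0) pmin(pmax((1 - age) / span, 0), 1) else
      as.numeric(age <= model@declineAge)
    f <- f * dec
  }
  f
}

## Expected total molecules for cells of given ages, scaled so the
## population (steady-state) average equals model@meanMolecules.
## Under the volume law, E[2^age] over f(a) = 2^(1-a) ln2 is 2 ln 2.
expectedMolecules <- function(age, model) {
  switch(model@expressionLaw,
         constant = rep(model@meanMolecules, length(age)),
         volume = model@meanMolecules * 2^age / (2 * log(2)))
}

## Per-sample axial volume weights for a sphero-cylinder of N samples:
## exact closed-form volume of each pixel-wide slab (hemispherical caps,
## cylindrical middle), with the outermost slabs clipped at the poles so
## the weights sum to the exact sphero-cylinder volume. A signal at
## uniform concentration then has a profile proportional to these.
axialVolumeWeights <- function(nSamples, lengthUm, radius, pitch) {
  dx <- 1 / pitch
  L <- lengthUm
  r <- min(radius, L / 2)
  ## cumulative volume from the left pole up to axial position d in [0,L]
  capG <- function(s) pi * (r * s^2 - s^3 / 3)  # cap portion, s in [0,r]
  Vtot <- pi * r^2 * (L - 2 * r) + (4 / 3) * pi * r^3
  Vcum <- function(d) {
    d <- pmin(pmax(d, 0), L)
    ifelse(d <= r, capG(d),
           ifelse(d <= L - r, capG(r) + pi * r^2 * (d - r),
                  Vtot - capG(L - d)))
  }
  ## slab boundaries centered on the cell; the outermost boundaries are
  ## pinned to the poles so the weights always sum to the exact volume
  ## (round() can make the sampled span miss a sub-pixel sliver at the
  ## tips, whose volume belongs to the end slabs)
  bounds <- (0:nSamples - nSamples / 2) * dx + L / 2
  bounds[1] <- 0
  bounds[nSamples + 1] <- L
  diff(Vcum(bounds))
}

#' Simulate a steady-state population with known recruitment timing
#'
#' Draws cell ages from the steady-state age distribution, lengths from
#' the growth law, and builds each cell's axial fluorescence profile as
#' the sum of (i) a diffuse component distributed over the cell volume
#' (per-sample weight proportional to the local cross-sectional volume
#' of a sphero-cylinder) and (ii) a midcell ring modeled as a Gaussian
#' of axial s.d. `ringSigma` centered on the cell midpoint, holding the
#' age-dependent fraction of molecules given by [midcellFraction()].
#' Optional per-cell lognormal noise multiplies the total; optional
#' Poisson counting noise perturbs every sample. Without noise, the sum
#' of each profile equals the cell's expected total fluorescence
#' exactly. Ground truth (age, midcell fraction, total) is recorded in
#' the sidecar retrievable with [groundTruth()].
#'
#' @param n Number of cells (>= 2).
#' @param law A [GrowthLaw-class].
#' @param model A [RecruitmentModel-class].
#' @param pixelPitch Pixels per um of the synthesized profiles.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param strain,replicateId,growthCondition Metadata strings.
#' @param constrictionAge Cells older than this age are flagged
#'   constricting (default 0.8).
#' @return A [CellPopulation-class] with ground-truth sidecar.
#' @examples
#' pop <- simulatePopulation(50, GrowthLaw(), RecruitmentModel(),
#'                           seed = 1)
#' head(groundTruth(pop))
#' @export
simulatePopulation <- function(n, law = GrowthLaw(),
                               model = RecruitmentModel(),
                               pixelPitch = 15.28, seed = NULL,
                               strain = "simulated",
                               replicateId = "r1",
                               growthCondition = "simulated",
                               constrictionAge = 0.8) {
  stopifnot(is(law, "GrowthLaw"), is(model, "RecruitmentModel"))
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("n must be a single integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  age <- sampleAges(n)
  len <- lengthFromAge(age, law)
  r <- law@diameter / 2
  frac <- midcellFraction(age, model)
  totalTrue <- expectedMolecules(age, model)
  total <- totalTrue
  if (model@noiseCv > 0) {
    sdlog <- sqrt(log(1 + model@noiseCv^2))
    total <- total * stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
  }
  dx <- 1 / pixelPitch
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    nS <- as.integer(round(len[i] * pixelPitch))
    w <- axialVolumeWeights(nS, len[i], r, pixelPitch)
    diffuse <- total[i] * (1 - frac[i]) * w / sum(w)
    prof <- diffuse
    if (frac[i] > 0) {
      centers <- (seq_len(nS) - (nS + 1) / 2) * dx
      m <- stats::pnorm(centers + dx / 2, 0, model@ringSigma) -
        stats::pnorm(centers - dx / 2, 0, model@ringSigma)
      prof <- prof + total[i] * frac[i] * m / sum(m)
    }
    if (model@countingNoise) {
      lam <- pmax(prof * model@photonGain, 0)
      prof <- stats::rpois(nS, lam) / model@photonGain
    }
    profs[[i]] <- prof
  }
  truth <- data.frame(
    cell_id = sprintf("sim_%06d", seq_len(n)),
    true_age = age,
    true_midcell_fraction = frac,
    true_total_F = total
  )
  CellPopulation(
    lengths = len, diameters = rep(law@diameter, n), profiles = profs,
    cellIds = truth$cell_id, constricting = age > constrictionAge,
    strain = strain, replicateId = replicateId,
    growthCondition = growthCondition, pixelPitch = pixelPitch,
    seed = seed, metadata = list(truth = truth)
  )
}
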