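## Small shared fixtures, built in code at test time.

## A quiet wrapper: most readers/analyses report record counts on
## stderr, which is noise inside tests.
quietly <- function(expr) suppressMessages(suppressWarnings(expr))

## Tiny deterministic population with hand-chosen profiles.
toyPopulation <- function() {
  pitch <- 15.28
  lens <- c(2.0, 2.5, 3.0)
  profs <- lapply(lens, function(L) {
    n <- round(L * pitch)
    rep(1, n)
  })
  CellPopulation(lengths = lens, diameters = rep(1, 3),
                 profiles = profs, strain = "toy", pixelPitch = pitch)
}

## Noise-free simulated population, constant expression, for exact
## downstream checks.
cleanSim <- function(n = 500, t0 = 0.25, seed = 101, ...) {
  simulatePopulation(
    n, GrowthLaw(),
    RecruitmentModel(t0True = t0, noiseCv = 0,
                     expressionLaw = "constant", ...),
    seed = seed)
}
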