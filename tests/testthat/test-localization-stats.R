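test_that("length ranks map to the steady-state ages", {
  expect_equal(assignAges(c(2, 3))$age, c(0, 1))
  expect_equal(assignAges(c(2, 2.5, 3))$age,
               c(0, log(0.75) / log(0.5), 1))
  expect_equal(assignAges(c(2, 2.5, 3))$age[2], 0.41504,
               tolerance = 1e-5)
  ## permutation invariance of the (length, age) pairing
  set.seed(3)
  lens <- runif(50, 2, 4)
  a1 <- assignAges(lens)
  perm <- sample(50)
  a2 <- assignAges(lens[perm])
  expect_equal(a2$age, a1$age[perm])
  ## monotone in rank, endpoints exact
  expect_true(all(diff(a1$age[order(a1$rank)]) > 0))
  expect_error(assignAges(2), "at least 2")
  expect_error(assignAges(c(2, -1)), "> 0")
})

test_that("assigned ages track true simulation ages closely", {
  pop <- cleanSim(n = 5000, seed = 77)
  ages <- assignAges(cellLengths(pop))$age
  expect_lt(mean(abs(ages - groundTruth(pop)$true_age)), 0.02)
})

test_that("sphero-cylinder volumes match hand geometry", {
  expect_equal(cellVolume(1, 1), (4 / 3) * pi * 0.5^3)
  expect_equal(cellVolume(3, 1), pi * 0.25 * 2 + (4 / 3) * pi * 0.125)
  expect_equal(cellVolume(3, 1), 2.0944, tolerance = 1e-4)
  L <- seq(1, 5, by = 0.1)
  expect_true(all(diff(cellVolume(L, 1)) > 0))
  expect_error(cellVolume(0.5, 1), "geometry")
})

test_that("fcplus limits: volume-uniform zero, all-inside total, hand case", {
  ## hand-worked case from precomputed integrals
  parts <- fcplusFromParts(60, 40, 3, 1)
  expect_equal(parts[["V_mid"]], 0.6283, tolerance = 1e-4)
  expect_equal(parts[["V_rest"]], 1.4661, tolerance = 1e-4)
  expect_equal(parts[["C_mid"]], 95.49, tolerance = 1e-3)
  expect_equal(parts[["C_rest"]], 27.28, tolerance = 1e-3)
  expect_equal(parts[["fcplus"]], 42.86, tolerance = 1e-3)

  ## volume-uniform profile (axial density proportional to the local
  ## cross-section) has equal concentrations, fcplus = 0
  m <- RecruitmentModel(t0True = 1, noiseCv = 0)
  pop <- simulatePopulation(30, GrowthLaw(), m, seed = 8)
  fc <- quietly(fcplus(pop))
  expect_lt(max(abs(fc$fcplus)), 1e-10)

  ## all fluorescence inside the window: fcplus equals the total
  pitch <- 15.28
  n <- round(3 * pitch)
  prof <- numeric(n)
  w <- which(abs((seq_len(n) - (n + 1) / 2) / pitch) < 0.2)
  prof[w] <- 5
  pop2 <- CellPopulation(lengths = 3, diameters = 1,
                         profiles = list(prof), pixelPitch = pitch)
  fc2 <- quietly(fcplus(pop2))
  expect_equal(fc2$fcplus, sum(prof), tolerance = 1e-12)

  ## short cells are excluded with a message and counted
  pop3 <- CellPopulation(lengths = c(1.6, 3), diameters = c(1, 1),
                         profiles = list(rep(1, round(1.6 * pitch)),
                                         rep(1, n)),
                         pixelPitch = pitch)
  expect_message(fc3 <- fcplus(pop3), "excluded 1")
  expect_equal(attr(fc3, "n_excluded"), 1L)
  expect_equal(nrow(fc3), 1L)
})

test_that("fcplus of simulated cells matches a numerical integration oracle", {
  ## independent oracle: compute F_mid by dense numerical integration
  ## of the continuous emission model (ring Gaussian + volume-uniform
  ## diffuse), then apply the defining concentration algebra
  sigma <- 0.1
  m <- RecruitmentModel(t0True = 0.2, riseWidth = 0.2,
                        plateauFraction = 0.7, ringSigma = sigma,
                        noiseCv = 0, expressionLaw = "constant")
  pop <- simulatePopulation(40, GrowthLaw(), m, seed = 55)
  truth <- groundTruth(pop)
  fc <- quietly(fcplus(pop))
  stopifnot(nrow(fc) == 40)
  for (i in seq_len(10)) {
    L <- fc$length_um[i]; d <- fc$diameter_um[i]
    frac <- truth$true_midcell_fraction[i]
    tot <- truth$true_total_F[i]
    r <- d / 2
    ## diffuse share of the window = window volume / cell volume
    vMid <- pi * r^2 * 0.8
    vCell <- cellVolume(L, d)
    ringIn <- (stats::pnorm(0.4, 0, sigma) -
               stats::pnorm(-0.4, 0, sigma)) /
      (stats::pnorm(L / 2, 0, sigma) - stats::pnorm(-L / 2, 0, sigma))
    fMid <- tot * (frac * ringIn + (1 - frac) * vMid / vCell)
    expected <- (fMid / vMid - (tot - fMid) / (vCell - vMid)) * vMid
    expect_equal(fc$fcplus[i], expected, tolerance = 0.01)
  }
})

test_that("age binning averages, bounds and conserves cells", {
  ## constant value: every occupied bin mean is that constant, CI ~ 0
  ages <- c(0.01, 0.02, 0.12, 0.12, 0.77, 1.0)
  cv <- binByAge(rep(3.5, 6), ages)
  df <- as.data.frame(cv)
  expect_equal(unique(df$mean[df$n > 0]), 3.5)
  expect_true(all(df$ci[df$n > 0] < 1e-12))
  ## single cell at 0.12 occupies only bin [0.10, 0.15)
  one <- as.data.frame(binByAge(2, 0.12))
  expect_equal(one$n[round(one$bin_center, 3) == 0.125], 1L)
  expect_equal(sum(one$n), 1L)
  ## age exactly 1 falls into the last (closed) bin
  expect_equal(df$n[length(df$n)], 1L)
  ## conservation of cells under random ages
  set.seed(12)
  aa <- runif(500)
  expect_equal(sum(as.data.frame(binByAge(rnorm(500), aa))$n), 500L)
  ## Student-t CI matches the quantile formula on one bin
  set.seed(13)
  v <- rnorm(100, 10, 2)
  cv2 <- as.data.frame(binByAge(v, rep(0.52, 100)))
  got <- cv2$ci[round(cv2$bin_center, 3) == 0.525]
  expect_equal(got, stats::qt(0.975, 99) * stats::sd(v) / 10,
               tolerance = 1e-12)
  expect_equal(got, 1.984 * stats::sd(v) / 10, tolerance = 0.05)
  expect_error(binByAge(1:3, c(0.1, 0.2)), "same length")
})

test_that("min-max normalization is affine-invariant and idempotent", {
  cv <- binByAge(c(0, 0, 5, 5, 10, 10),
                 c(0.01, 0.02, 0.26, 0.27, 0.51, 0.52))
  nm <- minmaxNormalize(cv)
  df <- as.data.frame(nm)
  expect_equal(sort(df$mean[df$n > 0]), c(0, 0.5, 1))
  ## idempotence
  expect_equal(as.data.frame(minmaxNormalize(nm)), df)
  ## commutes with positive affine maps of the input
  set.seed(14)
  vals <- rnorm(120)
  ages <- runif(120)
  base <- as.data.frame(minmaxNormalize(binByAge(vals, ages)))
  for (k in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    tr <- as.data.frame(minmaxNormalize(binByAge(a * vals + b, ages)))
    expect_equal(tr$mean, base$mean, tolerance = 1e-9)
  }
  ## degenerate constant curve errors
  expect_error(minmaxNormalize(binByAge(rep(1, 5), seq(0.1, 0.9, 0.2))),
               "degenerate")
})

test_that("replicate averaging pools bins and reflects between-replicate spread", {
  c1 <- binByAge(c(0, 1), c(0.12, 0.37))
  c2 <- binByAge(c(1, 0), c(0.13, 0.38))
  avg <- as.data.frame(averageReplicates(list(c1, c2)))
  expect_equal(avg$mean[avg$n > 0], c(0.5, 0.5))
  ## identical curves average to themselves with zero CI
  same <- averageReplicates(list(c1, c1))
  df <- as.data.frame(same)
  expect_equal(df$mean, as.data.frame(c1)$mean)
  expect_true(all(df$ci[df$n > 0] < 1e-12))
  ## noisy replicates of a known curve: truth within CI in most bins
  set.seed(15)
  hits <- 0; tot <- 0
  curves <- lapply(1:3, function(r) {
    ages <- runif(600)
    truthv <- sin(pi * ages)
    binByAge(truthv + rnorm(600, 0, 0.3), ages)
  })
  avg2 <- as.data.frame(averageReplicates(curves))
  for (b in which(avg2$n == 3)) {
    tot <- tot + 1
    truthb <- sin(pi * avg2$bin_center[b])
    hits <- hits + (abs(avg2$mean[b] - truthb) <= avg2$ci[b])
  }
  expect_gte(hits / tot, 0.9)
  expect_error(averageReplicates(list(c1)), "at least 2")
  expect_error(
    averageReplicates(list(c1, binByAge(1, 0.5, binWidth = 0.1))),
    "grids")
})

test_that("molecule calibration is linear in the fluorescence ratio", {
  cv <- binByAge(c(100, 75, 0), c(0.12, 0.42, 0.77))
  mol <- as.data.frame(moleculesAtMidcell(cv, meanTotalF = 100))
  occ <- mol[mol$n > 0, ]
  expect_equal(occ$mean, c(133, 99.75, 0))
  expect_error(moleculesAtMidcell(cv, 0), "positive")
})

test_that("per-circumference density scales inversely with diameter", {
  expect_equal(midcellDensityPerCircumference(0, 1), 0)
  expect_equal(midcellDensityPerCircumference(pi, 1), 1)
  expect_equal(midcellDensityPerCircumference(7, 0.5),
               2 * midcellDensityPerCircumference(7, 1))
  expect_error(midcellDensityPerCircumference(1, 0), "> 0")
})

test_that("concentration per volume is total fluorescence over cell volume", {
  pitch <- 15.28
  n <- round(3 * pitch)
  prof <- rep(cellVolume(3, 1) / n, n)  # sums to the cell volume
  pop <- CellPopulation(lengths = 3, diameters = 1,
                        profiles = list(prof), pixelPitch = pitch)
  expect_equal(concentrationPerVolume(pop), 1.0)
  ## linear in the profile
  pop2 <- CellPopulation(lengths = 3, diameters = 1,
                         profiles = list(2 * prof), pixelPitch = pitch)
  expect_equal(concentrationPerVolume(pop2), 2.0)
  ## zero profile
  pop3 <- CellPopulation(lengths = 3, diameters = 1,
                         profiles = list(numeric(n)), pixelPitch = pitch)
  expect_equal(concentrationPerVolume(pop3), 0)
})
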