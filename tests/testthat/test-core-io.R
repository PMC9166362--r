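test_that("population tables round-trip losslessly through csv and tsv", {
  pop <- simulatePopulation(100, seed = 42)
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    writePopulation(pop, path, dialect)
    back <- quietly(readPopulation(path, dialect))
    expect_identical(cellIds(back), cellIds(pop))
    expect_identical(cellLengths(back), cellLengths(pop))
    expect_identical(cellDiameters(back), cellDiameters(pop))
    expect_identical(constricting(back), constricting(pop))
    expect_identical(as.list(profiles(back)), as.list(profiles(pop)))
    expect_identical(pixelPitch(back), pixelPitch(pop))
    expect_identical(strain(back), strain(pop))
    expect_identical(replicateId(back), replicateId(pop))
    expect_identical(back@seed, pop@seed)
  }
})

test_that("simple tables read with lengths preserved and rows validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,length_um,diameter_um,profile",
    "a,2.0,1.0,\"1;1;1\"",   # profile length far off round(2*2) is fine at pitch 2
    "b,2.5,1.0,\"1;1;1;1;1\"",
    "c,3.0,1.0,\"1;1;1;1;1;1\""), path)
  pop <- quietly(readPopulation(path, pixelPitch = 2))
  expect_equal(nCells(pop), 3L)
  expect_identical(cellLengths(pop), c(2.0, 2.5, 3.0))

  ## one negative-length row is dropped, with a message
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,length_um,diameter_um,profile",
    "a,2.0,1.0,\"1;1;1;1\"",
    "bad,-1.0,1.0,\"1;1\"",
    "c,3.0,1.0,\"1;1;1;1;1;1\""), path2)
  expect_message(pop2 <- readPopulation(path2, pixelPitch = 2),
                 "dropped 1")
  expect_equal(nCells(pop2), 2L)
})

test_that("wide p0..pN profile blocks and missing diameters are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,length_um,diameter_um,p0,p1,p2,p3,p4,p5",
    "a,2.0,1.0,5,6,7,8,,",
    "b,3.0,,1,2,3,4,5,6"), path)
  pop <- quietly(readPopulation(path, pixelPitch = 2))
  expect_equal(nCells(pop), 2L)
  expect_equal(as.list(profiles(pop))[[1]], c(5, 6, 7, 8))
  expect_equal(as.list(profiles(pop))[[2]], 1:6 + 0)
  expect_equal(cellDiameters(pop)[2], 1.0)  # imputed median
})

test_that("precomputed total/midcell fluorescence columns are accepted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,length_um,diameter_um,total_F,F_mid",
               "a,3.0,1.0,100,60"), path)
  ## a single row cannot be age-analyzed but fcplus must reproduce the
  ## integrals it was built from
  pop <- quietly(readPopulation(path))
  fc <- quietly(fcplus(pop))
  expect_equal(fc$F_mid, 60, tolerance = 1e-12)
  expect_equal(fc$total_F, 100, tolerance = 1e-12)
  expect_equal(fc$fcplus, fcplusFromParts(60, 40, 3, 1)[["fcplus"]])
})

test_that("format errors name the offending column and empty input fails", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,diameter_um,profile", "a,1.0,\"1;1\""), path)
  expect_error(quietly(readPopulation(path)), "length_um")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,length_um,diameter_um,profile",
               "a,-2.0,1.0,\"1;1;1;1\""), path2)
  expect_error(quietly(readPopulation(path2, pixelPitch = 2)),
               "empty input")
})

test_that("an empty population writes a header-only file", {
  pop <- CellPopulation(lengths = numeric(), diameters = numeric(),
                        profiles = list())
  path <- withr::local_tempfile(fileext = ".csv")
  writePopulation(pop, path)
  expect_length(readLines(path), 1L)
})

test_that("background subtraction is exact, identity-preserving and additive", {
  expect_equal(subtractBackground(c(5, 5, 5), 5), c(0, 0, 0))
  p <- c(3.2, 7.5, 0.1, 9)
  expect_identical(subtractBackground(p, 0), p)
  ## additivity
  expect_equal(subtractBackground(p, 4.2),
               subtractBackground(subtractBackground(p, 1.5), 2.7))
  ## negative results preserved
  expect_true(any(subtractBackground(p, 4) < 0))
  expect_error(subtractBackground(p, -1), ">= 0")
})

test_that("modal estimation finds the dominant value and camera background", {
  expect_equal(estimateModal(c(rep(1, 9), 2)), 1, tolerance = 0.51)
  expect_equal(estimateModal(rep(7.3, 25)), 7.3)
  expect_error(estimateModal(1:9), "at least 10")
  ## a profile with a dominant zero mode plus offset recovers the offset
  set.seed(5)
  base <- c(rep(0, 900), runif(100, 5, 50))
  est <- estimateModal(base + 40)
  expect_lt(abs(est - 40), 1)  # within one bin width
  ## Gaussian background: mode near the mean, within a bin width
  set.seed(6)
  g <- rnorm(1e5, 100, 5)
  expect_lt(abs(estimateModal(g) - 100), 1)
  ## reorder invariance
  set.seed(7)
  expect_identical(estimateModal(g), estimateModal(sample(g)))
})

test_that("profile alignment recovers integer, zero and sub-sample shifts", {
  pitch <- 15.28
  x <- seq(0, 4 * pi, length.out = 60)
  ref <- exp(-(x - 2 * pi)^2) + 0.3 * sin(x)

  ## integer shift: signal displaced by +2 samples
  sig <- c(ref[1], ref[1], ref[1:58])
  al <- alignProfile(ref, sig, maxShift = 0.5, pitch = pitch)
  expect_lt(abs(al$shift * pitch - 2), 0.05)

  ## identity
  expect_lt(abs(alignProfile(ref, ref, 0.5, pitch)$shift), 1e-9)

  ## sub-sample shift of 0.4 samples via band-limited interpolation
  shifted <- stats::spline(seq_along(ref), ref,
                           xout = seq_along(ref) - 0.4)$y
  al2 <- alignProfile(ref, shifted, 0.5, pitch)
  expect_lt(abs(al2$shift * pitch - 0.4), 0.1)

  ## antisymmetry within interpolation tolerance
  al3 <- alignProfile(sig, ref, 0.5, pitch)
  expect_lt(abs(al3$shift + al$shift) * pitch, 0.1)

  ## flat signal errors
  expect_error(alignProfile(ref, rep(1, 60), 0.5, pitch), "flat")
  ## aligned profile matches the reference where the overlap is clean
  expect_lt(max(abs(al$aligned[5:55] - ref[5:55])), 0.05)
})
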