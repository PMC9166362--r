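#' Read a per-cell measurement table
#'
#' Reads a delimited per-cell table (one row per cell) into a
#' [CellPopulation-class]. The only mandatory column is `length_um`;
#' the axial profile may come as a packed single column `profile`
#' (values joined by `;`) or as a wide block of columns `p0, p1, ...`
#' (ragged rows padded with empty cells). Tables carrying only
#' precomputed integrated fluorescence (`total_F` and `F_mid`, the
#' integral over the central 0.8 um) instead of a profile are also
#' accepted: a profile consistent with those two integrals (uniform
#' inside and outside the window) is synthesized at `pixelPitch`, which
#' leaves every downstream window statistic unchanged.
#'
#' Rows failing validation (non-positive or missing length, non-positive
#' diameter, unparseable profile, profile length inconsistent with
#' `round(length_um * pixelPitch)` by more than one sample) are dropped
#' and counted in a message to stderr. Missing diameters are imputed
#' with the population median diameter.
#'
#' @param path File to read.
#' @param dialect `"auto"` (by extension), `"csv"`, `"tsv"` or
#'   `"xlsx"` (needs the readxl package).
#' @param pixelPitch Pixels per um of the stored profiles; overridden by
#'   a `pixel_pitch` column if present.
#' @param strain,replicateId,growthCondition Metadata defaults used when
#'   the table has no such columns.
#' @return A validated [CellPopulation-class].
#' @seealso [writePopulation()]
#' @export
readPopulation <- function(path,
                           dialect = c("auto", "csv", "tsv", "xlsx"),
                           pixelPitch = 15.28,
                           strain = "unspecified", replicateId = "r1",
                           growthCondition = "unspecified") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- switch(tolower(tools::file_ext(path)),
                      tsv = "tsv", txt = "tsv", xlsx = "xlsx", "csv")
  tab <- if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path))
  } else {
    as.data.frame(data.table::fread(
      path, sep = if (dialect == "tsv") "\t" else ",",
      header = TRUE, colClasses = list(character = "cell_id")))
  }
  if (!"length_um" %in% names(tab))
    stop("mandatory column missing: length_um")

  scalarMeta <- function(col, default) {
    if (col %in% names(tab) && nrow(tab)) tab[[col]][1] else default
  }
  pitch <- as.numeric(scalarMeta("pixel_pitch", pixelPitch))
  strain <- as.character(scalarMeta("strain", strain))
  replicateId <- as.character(scalarMeta("replicate_id", replicateId))
  growthCondition <- as.character(
    scalarMeta("growth_condition", growthCondition))
  seed <- scalarMeta("seed", NA)
  seed <- if (is.na(seed)) NULL else as.integer(seed)

  nIn <- nrow(tab)
  if (!nIn) stop("empty input: no data rows in ", path)
  len <- suppressWarnings(as.numeric(tab$length_um))
  dia <- if ("diameter_um" %in% names(tab))
    suppressWarnings(as.numeric(tab$diameter_um)) else rep(NA_real_, nIn)
  nImputed <- sum(is.na(dia))
  if (nImputed > 0 && nImputed < nIn) {
    dia[is.na(dia)] <- stats::median(dia, na.rm = TRUE)
    message("readPopulation: imputed median diameter for ", nImputed,
            " row(s)")
  } else if (nImputed == nIn) {
    dia <- rep(1.0, nIn)
    message("readPopulation: no diameter column; defaulting to 1 um")
  }

  wide <- grep("^p[0-9]+$", names(tab), value = TRUE)
  profs <- vector("list", nIn)
  if ("profile" %in% names(tab)) {
    for (i in seq_len(nIn))
      profs[[i]] <- suppressWarnings(as.numeric(
        strsplit(as.character(tab$profile[i]), ";", fixed = TRUE)[[1]]))
  } else if (length(wide)) {
    wide <- wide[order(as.integer(sub("^p", "", wide)))]
    m <- as.matrix(tab[, wide, drop = FALSE])
    storage.mode(m) <- "double"
    for (i in seq_len(nIn)) {
      v <- unname(m[i, ])
      profs[[i]] <- v[seq_len(max(which(!is.na(v)), 0L))]
    }
  } else if (all(c("total_F", "F_mid") %in% names(tab))) {
    for (i in seq_len(nIn))
      profs[[i]] <- syntheticWindowProfile(
        len[i], as.numeric(tab$total_F[i]), as.numeric(tab$F_mid[i]),
        pitch)
  } else {
    stop("mandatory column missing: need 'profile', a p0.. block, ",
         "or 'total_F' + 'F_mid'")
  }

  constr <- if ("constricting" %in% names(tab))
    as.logical(tab$constricting) else rep(FALSE, nIn)
  constr[is.na(constr)] <- FALSE
  ids <- if ("cell_id" %in% names(tab)) as.character(tab$cell_id) else
    sprintf("cell_%04d", seq_len(nIn))

  nSamp <- vapply(profs, length, 0L)
  badProf <- vapply(profs, function(p)
    !length(p) || anyNA(p) || any(!is.finite(p)), TRUE)
  ok <- !is.na(len) & len > 0 & !is.na(dia) & dia > 0 & len >= dia &
    !badProf & abs(nSamp - round(len * pitch)) <= 1
  if (!any(ok)) stop("empty input: no valid rows in ", path)
  if (any(!ok))
    message("readPopulation: dropped ", sum(!ok), " invalid row(s)")

  CellPopulation(lengths = len[ok], diameters = dia[ok],
                 profiles = profs[ok], cellIds = ids[ok],
                 constricting = constr[ok], strain = strain,
                 replicateId = replicateId,
                 growthCondition = growthCondition,
                 pixelPitch = pitch, seed = seed)
}

## Uniform-inside / uniform-outside profile reproducing given total and
## midcell-window integrals at the stated pitch: the window samples get
## a constant value b with b * sum(weights) = fMid, the remaining
## samples share totalF - (window sum) uniformly.
syntheticWindowProfile <- function(lengthUm, totalF, fMid, pitch,
                                   window = 0.8) {
  n <- max(as.integer(round(lengthUm * pitch)), 2L)
  w <- windowWeights(n, pitch, window)
  inW <- w > 0
  prof <- numeric(n)
  b <- fMid / sum(w)
  prof[inW] <- b
  if (any(!inW)) prof[!inW] <- (totalF - b * sum(inW)) / sum(!inW)
  prof
}

#' Write a CellPopulation to a delimited table
#'
#' Writes one row per cell with columns `cell_id`, `length_um`,
#' `diameter_um`, `constricting`, a packed `profile` column (values
#' joined by `;` at 17 significant digits, so numeric round-trip through
#' [readPopulation()] is lossless), and constant metadata columns
#' (`strain`, `replicate_id`, `growth_condition`, `pixel_pitch`,
#' `seed`). An empty population yields a header-only file. If the
#' population carries a simulator ground-truth sidecar it is written
#' next to `path` as `<path>.truth.<ext>`.
#'
#' @param pop A [CellPopulation-class].
#' @param path Output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writePopulation <- function(pop, path, dialect = c("csv", "tsv")) {
  stopifnot(is(pop, "CellPopulation"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  n <- nCells(pop)
  num <- function(x) sprintf("%.17g", x)
  dt <- data.table::data.table(
    cell_id = cellIds(pop),
    length_um = num(cellLengths(pop)),
    diameter_um = num(cellDiameters(pop)),
    constricting = constricting(pop),
    profile = vapply(as.list(profiles(pop)),
                     function(p) paste(num(p), collapse = ";"), ""),
    strain = rep(pop@strain, n),
    replicate_id = rep(pop@replicateId, n),
    growth_condition = rep(pop@growthCondition, n),
    pixel_pitch = rep(num(pop@pixelPitch), n),
    seed = rep(if (is.null(pop@seed)) NA_integer_ else pop@seed, n)
  )
  data.table::fwrite(dt, path, sep = sep)
  truth <- groundTruth(pop)
  if (!is.null(truth)) {
    ext <- tools::file_ext(path)
    tpath <- sub(paste0("\\.", ext, "$"), paste0(".truth.", ext), path)
    tdt <- data.table::as.data.table(lapply(truth, function(col)
      if (is.numeric(col)) num(col) else col))
    data.table::fwrite(tdt, tpath, sep = sep)
  }
  invisible(path)
}

#' Subtract a scalar background from a fluorescence profile
#'
#' Decrements every sample by the modal background value. Negative
#' results are preserved, never clipped: clipping would bias the
#' midcell surplus upward at low signal.
#'
#' @param profile Numeric fluorescence samples.
#' @param background Scalar background (>= 0), typically from
#'   [estimateModal()].
#' @return `profile - background`.
#' @export
subtractBackground <- function(profile, background) {
  if (length(background) != 1L || is.na(background) || background < 0)
    stop("background must be a single value >= 0")
  profile - background
}

#' Estimate the modal (background) intensity of a sample of pixel values
#'
#' Histogram mode: bin width is the larger of 1 intensity unit and the
#' Freedman-Diaconis width, the mode is the center of the tallest bin,
#' and ties break toward the lowest bin. The mode of a camera image's
#' intensity histogram is the conventional estimate of its additive
#' background.
#'
#' @param values At least 10 finite intensity values.
#' @return The modal value (a bin center; exact for constant input).
#' @export
estimateModal <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("insufficient data: need at least 10 samples")
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  fd <- 2 * stats::IQR(values) / length(values)^(1 / 3)
  bw <- max(1, fd)
  ## bins centered on integers when the width is the 1-unit floor, so
  ## integer-valued camera data yields the exact modal intensity
  start <- if (bw == 1) floor(rng[1]) - 0.5 else rng[1] - bw / 2
  breaks <- seq(start, rng[2] + bw, by = bw)
  counts <- tabulate(findInterval(values, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  k <- which.max(counts)  # which.max takes the first (lowest) tie
  breaks[k] + bw / 2
}

#' Align a fluorescence profile to a reference by 1-D cross-correlation
#'
#' Estimates the axial shift of `signal` relative to `reference` (both
#' sampled at the same pitch) as the lag maximizing their Pearson
#' cross-correlation within `+/- maxShift`, refined to sub-sample
#' precision by parabolic interpolation of the correlation peak. The
#' returned `aligned` profile is `signal` translated by the negated
#' shift (linear interpolation, edges padded with the profile's end
#' values), i.e. registered onto the reference.
#'
#' @param reference Numeric profile (e.g. phase-contrast derived).
#' @param signal Numeric fluorescence profile, same length and pitch.
#' @param maxShift Maximum shift searched, um; must not exceed a
#'   quarter of the profile length.
#' @param pitch Pixels per um (default 15.28).
#' @return A list with `shift` (um, positive when `signal` is displaced
#'   toward higher indices relative to `reference`) and `aligned`.
#' @export
alignProfile <- function(reference, signal, maxShift, pitch = 15.28) {
  if (length(reference) != length(signal))
    stop("reference and signal must have the same length")
  n <- length(signal)
  if (maxShift > n / pitch / 4)
    stop("maxShift must be <= profile length / 4")
  if (stats::sd(signal) == 0 || stats::sd(reference) == 0)
    stop("alignment error: flat (zero-variance) profile")
  kMax <- max(1L, as.integer(round(maxShift * pitch)))
  lags <- (-kMax):kMax
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- reference[seq_len(n - k)]
      b <- signal[(1 + k):n]
    } else {
      a <- reference[(1 - k):n]
      b <- signal[seq_len(n + k)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) -Inf
    else stats::cor(a, b)
  }, 0)
  i0 <- which.max(cc)
  k0 <- lags[i0]
  delta <- 0
  if (i0 > 1 && i0 < length(lags) && all(is.finite(cc[(i0 - 1):(i0 + 1)]))) {
    cm <- cc[i0 - 1]; c0 <- cc[i0]; cp <- cc[i0 + 1]
    den <- cm - 2 * c0 + cp
    if (den < 0) delta <- 0.5 * (cm - cp) / den
  }
  shiftSamples <- k0 + delta
  ## translate signal by -shift: aligned[i] = signal[i + shift]
  pos <- seq_len(n) + shiftSamples
  pos <- pmin(pmax(pos, 1), n)
  lo <- floor(pos); hi <- ceiling(pos); fr <- pos - lo
  aligned <- signal[lo] * (1 - fr) + signal[hi] * fr
  list(shift = shiftSamples / pitch, aligned = aligned)
}
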