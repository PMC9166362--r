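## Known configuration keys per subcommand, with validation ranges.
## Shared analysis defaults mirror the measurement pipeline's printed
## constants: 0.8 um midcell window, 5% age bins, 95% CI, 15.28 px/um,
## 133 molecules per average cell.
configSchema <- function() {
  num <- function(lo, hi, default)
    list(type = "numeric", lo = lo, hi = hi, default = default)
  str <- function(default, choices = NULL)
    list(type = "character", default = default, choices = choices)
  flag <- function(default) list(type = "logical", default = default)
  common <- list(
    pixel_pitch = num(1e-6, Inf, 15.28),
    midcell_width = num(1e-6, Inf, 0.8),
    bin_width = num(1e-6, 1, 0.05),
    ci_level = num(1e-6, 1 - 1e-6, 0.95),
    seed = num(-2^31, 2^31, 1),
    persistence = num(1, 100, 2),
    tol_rel = num(0, 1, 0.01)
  )
  list(
    simulate = c(common, list(
      n_cells = num(2, Inf, 1000),
      birth_length = num(1e-6, Inf, 2.0),
      diameter = num(1e-6, Inf, 0.9),
      growth_mode = str("exponential", c("exponential", "linear")),
      t0_true = num(0, 1, 0.25),
      rise_width = num(1e-9, 1, 0.2),
      plateau_fraction = num(1e-9, 1, 0.6),
      decline_age = num(0, 1, NA_real_),
      rise_shape = str("linear", c("linear", "smoothstep")),
      expression_law = str("volume", c("volume", "constant")),
      mean_molecules = num(1e-9, Inf, 133),
      ring_sigma = num(1e-9, 0.4 - 1e-9, 0.1),
      noise_cv = num(0, Inf, 0.1),
      counting_noise = flag(FALSE),
      photon_gain = num(1e-9, Inf, 100),
      constriction_age = num(0, 1, 0.8),
      strain = str("simulated"), replicate_id = str("r1"),
      out = str("population.csv"))),
    analyze = c(common, list(
      input = str(NA_character_),
      out_cells = str("fcplus_cells.csv"),
      out_curve = str("fcplus_curve.csv"))),
    timing = c(common, list(
      input = str(NA_character_),
      protein = str("protein"),
      strain = str("unspecified"), replicate_id = str("r1"),
      out = str("timing.csv"))),
    compare = c(common, list(
      parental = str(NA_character_), mutant = str(NA_character_),
      statistic = str("t0", c("t0", "t_half")),
      out = str("comparison.csv"))),
    demograph = c(common, list(
      input = str(NA_character_),
      normalize_per_cell = flag(FALSE),
      shared_lo = num(-Inf, Inf, NA_real_),
      shared_hi = num(-Inf, Inf, NA_real_),
      out = str("demograph.tiff")))
  )
}

#' Validate a run configuration
#'
#' Merges a YAML configuration file and/or an override list against
#' the schema of one pipeline subcommand: unknown keys are rejected by
#' name, every numeric parameter is checked against its documented
#' range, and missing keys take their documented defaults.
#'
#' @param subcommand One of `"simulate"`, `"analyze"`, `"timing"`,
#'   `"compare"`, `"demograph"`.
#' @param configFile Optional YAML file; keys may sit at top level or
#'   under a section named after the subcommand.
#' @param overrides Named list overriding file values.
#' @return Named list of validated parameters.
#' @export
readRunConfig <- function(subcommand, configFile = NULL,
                          overrides = list()) {
  schema <- configSchema()
  if (!subcommand %in% names(schema))
    stop("unknown subcommand: ", subcommand)
  sch <- schema[[subcommand]]
  cfg <- list()
  if (!is.null(configFile)) {
    if (!file.exists(configFile))
      stop("config file not found: ", configFile)
    y <- yaml::yaml.load_file(configFile)
    if (!is.null(y[[subcommand]]) && is.list(y[[subcommand]])) {
      top <- y[!vapply(y, is.list, TRUE)]
      cfg <- utils::modifyList(top, y[[subcommand]])
    } else cfg <- y
  }
  cfg <- utils::modifyList(cfg, overrides)
  bad <- setdiff(names(cfg), names(sch))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  out <- lapply(names(sch), function(k) {
    v <- if (k %in% names(cfg)) cfg[[k]] else sch[[k]]$default
    s <- sch[[k]]
    if (s$type == "numeric" && !is.null(v) && !is.na(v)) {
      v <- as.numeric(v)
      if (!is.finite(v) && is.finite(s$lo))
        stop("configuration key '", k, "' must be a finite number")
      if (v < s$lo || v > s$hi)
        stop("configuration key '", k, "' out of range [",
             s$lo, ", ", s$hi, "]: ", v)
    }
    if (s$type == "logical") v <- isTRUE(as.logical(v))
    if (s$type == "character" && !is.null(s$choices) && !is.na(v) &&
        !v %in% s$choices)
      stop("configuration key '", k, "' must be one of: ",
           paste(s$choices, collapse = ", "))
    v
  })
  names(out) <- names(sch)
  out
}

writeManifest <- function(dir, subcommand, cfg, inputs, counts) {
  inputs <- inputs[vapply(inputs, function(p)
    is.character(p) && !is.na(p) && file.exists(p), TRUE)]
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("FCplus")),
    r_version = as.character(getRversion()),
    config = cfg,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    record_counts = counts
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
}

#' Run one pipeline stage
#'
#' Single entry point wiring the stages into reproducible runs; the
#' same interface is exposed as a command-line script in
#' `system.file("scripts", "fcplus", package = "FCplus")`. Outputs are
#' deterministic for a fixed configuration and seed, and every run
#' writes a `manifest.yaml` (configuration echo, input checksums,
#' versions, per-stage record counts) next to its outputs.
#'
#' * `simulate`: writes the simulated population table plus its
#'   ground-truth sidecar.
#' * `analyze`: per-cell table in, per-cell FCPlus table and
#'   age-binned curve table (`bin_center`, `mean`, `ci`, `n`) out.
#' * `timing`: per-cell table or binned-curve table in, one-row timing
#'   table out.
#' * `compare`: two timing tables in, strain comparison out.
#' * `demograph`: per-cell table in, raster or matrix out.
#'
#' @param subcommand Stage name.
#' @param configFile,overrides See [readRunConfig()].
#' @param outDir Directory for outputs and the manifest (created if
#'   needed).
#' @return Invisibly, a named list of the paths written.
#' @export
runPipeline <- function(subcommand, configFile = NULL,
                        overrides = list(), outDir = ".") {
  cfg <- readRunConfig(subcommand, configFile, overrides)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  counts <- list()
  inputs <- list()
  outPath <- function(p) if (is.na(p)) p else
    if (dirname(p) == ".") file.path(outDir, p) else p

  if (subcommand == "simulate") {
    law <- GrowthLaw(cfg$birth_length, cfg$growth_mode, cfg$diameter)
    model <- RecruitmentModel(
      t0True = cfg$t0_true, riseWidth = cfg$rise_width,
      plateauFraction = cfg$plateau_fraction,
      declineAge = cfg$decline_age, riseShape = cfg$rise_shape,
      expressionLaw = cfg$expression_law,
      meanMolecules = cfg$mean_molecules, ringSigma = cfg$ring_sigma,
      noiseCv = cfg$noise_cv, countingNoise = cfg$counting_noise,
      photonGain = cfg$photon_gain)
    pop <- simulatePopulation(
      cfg$n_cells, law, model, pixelPitch = cfg$pixel_pitch,
      seed = as.integer(cfg$seed), strain = cfg$strain,
      replicateId = cfg$replicate_id,
      constrictionAge = cfg$constriction_age)
    p <- outPath(cfg$out)
    writePopulation(pop, p)
    paths$population <- p
    counts$cells <- nCells(pop)
  } else if (subcommand == "analyze") {
    if (is.na(cfg$input)) stop("'input' is required for analyze")
    inputs$input <- cfg$input
    pop <- readPopulation(cfg$input, pixelPitch = cfg$pixel_pitch)
    fc <- fcplus(pop, cfg$midcell_width)
    ages <- assignAges(fc$length_um)$age
    fc$age <- ages
    curve <- binByAge(fc$fcplus, ages, cfg$bin_width, cfg$ci_level)
    pc <- outPath(cfg$out_cells)
    pv <- outPath(cfg$out_curve)
    data.table::fwrite(data.table::as.data.table(fc), pc)
    data.table::fwrite(
      data.table::as.data.table(as.data.frame(curve)), pv)
    paths$cells <- pc
    paths$curve <- pv
    counts$cells_in <- nCells(pop)
    counts$cells_analyzed <- nrow(fc)
    counts$cells_excluded_short <- attr(fc, "n_excluded")
  } else if (subcommand == "timing") {
    if (is.na(cfg$input)) stop("'input' is required for timing")
    inputs$input <- cfg$input
    head <- names(data.table::fread(cfg$input, nrows = 0))
    res <- if (all(c("bin_center", "mean", "n") %in% head)) {
      tab <- data.table::fread(cfg$input)
      curve <- new("BinnedCurve", binCenters = tab$bin_center,
                   mean = ifelse(is.na(tab$mean), NA_real_, tab$mean),
                   ciHalfwidth = as.numeric(tab$ci),
                   count = as.integer(tab$n), valueKind = "fcplus",
                   binWidth = cfg$bin_width, ciLevel = cfg$ci_level)
      t0 <- estimateT0(curve, cfg$persistence, cfg$tol_rel)
      th <- estimateThalf(curve, cfg$persistence, cfg$tol_rel)
      data.frame(protein = cfg$protein, strain = cfg$strain,
                 replicate_id = cfg$replicate_id, t0 = t0,
                 t_half = th$t_half, fc_max = th$fc_max,
                 n_cells = sum(tab$n))
    } else {
      pop <- readPopulation(cfg$input, pixelPitch = cfg$pixel_pitch)
      estimateTiming(pop, cfg$protein, cfg$midcell_width,
                     cfg$bin_width, cfg$ci_level, cfg$persistence,
                     cfg$tol_rel)
    }
    p <- outPath(cfg$out)
    data.table::fwrite(data.table::as.data.table(res), p)
    paths$timing <- p
    counts$replicates <- nrow(res)
  } else if (subcommand == "compare") {
    if (is.na(cfg$parental) || is.na(cfg$mutant))
      stop("'parental' and 'mutant' timing tables are required")
    inputs$parental <- cfg$parental
    inputs$mutant <- cfg$mutant
    par <- as.data.frame(data.table::fread(cfg$parental))
    mut <- as.data.frame(data.table::fread(cfg$mutant))
    res <- compareStrains(par, mut, cfg$statistic)
    p <- outPath(cfg$out)
    data.table::fwrite(data.table::as.data.table(res), p)
    paths$comparison <- p
    counts$n_parental <- nrow(par)
    counts$n_mutant <- nrow(mut)
  } else if (subcommand == "demograph") {
    if (is.na(cfg$input)) stop("'input' is required for demograph")
    inputs$input <- cfg$input
    pop <- readPopulation(cfg$input, pixelPitch = cfg$pixel_pitch)
    d <- buildDemograph(pop, cfg$normalize_per_cell)
    shared <- if (!is.na(cfg$shared_lo) && !is.na(cfg$shared_hi))
      c(cfg$shared_lo, cfg$shared_hi) else NULL
    p <- outPath(cfg$out)
    writeDemograph(d, p, sharedScale = shared)
    paths$demograph <- p
    counts$cells <- nCells(pop)
  }
  writeManifest(outDir, subcommand, cfg, inputs, counts)
  paths$manifest <- file.path(outDir, "manifest.yaml")
  invisible(paths)
}
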