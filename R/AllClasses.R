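#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges NumericList
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' CellPopulation: one replicate's set of measured cells
#'
#' A `CellPopulation` holds the per-cell measurements of one immunolabeling
#' replicate: cell identifiers, lengths and diameters (um), an optional
#' constriction flag, and the background-subtracted axial fluorescence
#' profile of each cell sampled at a common pixel pitch (pixels per um).
#' Profile sample 0 lies at one pole, the last sample at the other pole;
#' fixed cells carry no polarity, so the orientation is arbitrary and all
#' downstream windows are symmetric about the cell center.
#'
#' @slot cells A [S4Vectors::DataFrame] with columns `cell_id` (character),
#'   `length_um`, `diameter_um` (numeric, um) and `constricting` (logical).
#' @slot profiles An [IRanges::NumericList], one numeric vector per cell;
#'   `length(profiles[[i]])` equals `round(length_um[i] * pixelPitch)`
#'   within one sample. Values may be negative after background
#'   subtraction.
#' @slot strain,replicateId,growthCondition Single strings of metadata.
#' @slot pixelPitch Pixels per um shared by all profiles (default 15.28).
#' @slot seed Integer RNG seed for simulated populations, or `NULL`.
#' @slot metadata Free-form list; the simulator stores its ground-truth
#'   sidecar (`truth`) here.
#'
#' @seealso [CellPopulation()] for the constructor, [readPopulation()],
#'   [simulatePopulation()].
#' @exportClass CellPopulation
setClass("CellPopulation",
  slots = c(
    cells = "DataFrame",
    profiles = "NumericList",
    strain = "character",
    replicateId = "character",
    growthCondition = "character",
    pixelPitch = "numeric",
    seed = "integerOrNULL",
    metadata = "list"
  )
)

setValidity("CellPopulation", function(object) {
  msg <- character()
  need <- c("cell_id", "length_um", "diameter_um", "constricting")
  miss <- setdiff(need, colnames(object@cells))
  if (length(miss))
    msg <- c(msg, paste0("cells is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (!length(miss)) {
    len <- object@cells$length_um
    dia <- object@cells$diameter_um
    if (any(!is.finite(len)) || any(len <= 0))
      msg <- c(msg, "all cell lengths must be finite and > 0")
    if (any(!is.finite(dia)) || any(dia <= 0))
      msg <- c(msg, "all cell diameters must be finite and > 0")
    if (!length(msg) && any(len < dia))
      msg <- c(msg, "length must be >= diameter (rod or sphere)")
    if (length(object@profiles) != nrow(object@cells))
      msg <- c(msg, "profiles must have one element per cell")
    else if (nrow(object@cells) && !length(msg)) {
      ns <- lengths(object@profiles)
      expected <- round(len * object@pixelPitch)
      if (any(abs(ns - expected) > 1))
        msg <- c(msg, paste0(sum(abs(ns - expected) > 1), " profile(s) ",
                             "have a sample count inconsistent with ",
                             "round(length_um * pixelPitch) +/- 1"))
      tot <- sum(unlist(object@profiles, use.names = FALSE))
      if (length(tot) && !is.finite(tot))
        msg <- c(msg, "profile values must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GrowthLaw: single-cell length growth over the division cycle
#'
#' Maps division-cycle age (0 at birth, 1 at division) to cell length. In
#' steady state a cell exactly doubles its birth length over one cycle,
#' which both supported modes enforce: `exponential` gives
#' `birth_length * 2^age`, `linear` gives `birth_length * (1 + age)`.
#'
#' @slot birthLength Length at age 0, um.
#' @slot mode `"exponential"` or `"linear"`.
#' @slot diameter Cell diameter, um, constant over the cycle.
#' @seealso [GrowthLaw()], [lengthFromAge()].
#' @exportClass GrowthLaw
setClass("GrowthLaw",
  slots = c(birthLength = "numeric", mode = "character",
            diameter = "numeric")
)

setValidity("GrowthLaw", function(object) {
  msg <- character()
  if (length(object@birthLength) != 1L || object@birthLength <= 0)
    msg <- c(msg, "birthLength must be a single positive number (um)")
  if (length(object@diameter) != 1L || object@diameter <= 0)
    msg <- c(msg, "diameter must be a single positive number (um)")
  if (!length(msg) && object@birthLength < object@diameter)
    msg <- c(msg, "birthLength must be >= diameter")
  if (!object@mode %in% c("exponential", "linear"))
    msg <- c(msg, "mode must be 'exponential' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' RecruitmentModel: ground-truth midcell recruitment for the simulator
#'
#' Describes, as a function of division-cycle age, which fraction of a
#' cell's fluorescent molecules sits in the midcell ring: zero before the
#' onset age `t0True`, a continuous rise (linear ramp or smoothstep) of
#' duration `riseWidth` up to `plateauFraction`, a plateau, and an
#' optional linear decline to zero after `declineAge`.
#'
#' @slot t0True Onset age in `[0, 1)`; `t0True = 1` means the protein
#'   never recruits (null model).
#' @slot riseWidth Age-fraction duration of the rise (> 0);
#'   `t0True + riseWidth <= 1`.
#' @slot plateauFraction Fraction of cellular molecules at midcell at
#'   plateau, in `(0, 1]`.
#' @slot declineAge Age after which the midcell fraction decays linearly
#'   to zero at age 1, or `NA` for no decline.
#' @slot riseShape `"linear"` or `"smoothstep"`.
#' @slot expressionLaw `"volume"` (expected molecules proportional to
#'   cell volume, i.e. to `2^age` under exponential growth) or
#'   `"constant"`.
#' @slot meanMolecules Culture-average expected molecules per cell
#'   (scales total fluorescence; default 133).
#' @slot ringSigma Axial s.d. of the midcell Gaussian component, um;
#'   must be < 0.4 so the ring mass sits mostly inside the 0.8 um window.
#' @slot noiseCv Coefficient of variation of per-cell multiplicative
#'   lognormal noise on the total fluorescence (>= 0).
#' @slot countingNoise Logical; Poisson-like per-sample noise.
#' @slot photonGain Photons per fluorescence unit used by the counting
#'   noise (larger = less noise).
#' @seealso [RecruitmentModel()], [midcellFraction()],
#'   [simulatePopulation()].
#' @exportClass RecruitmentModel
setClass("RecruitmentModel",
  slots = c(t0True = "numeric", riseWidth = "numeric",
            plateauFraction = "numeric", declineAge = "numeric",
            riseShape = "character", expressionLaw = "character",
            meanMolecules = "numeric", ringSigma = "numeric",
            noiseCv = "numeric", countingNoise = "logical",
            photonGain = "numeric")
)

setValidity("RecruitmentModel", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@t0True) || object@t0True < 0 || object@t0True > 1)
    msg <- c(msg, "t0True must be in [0, 1]")
  if (!one(object@riseWidth) || object@riseWidth <= 0)
    msg <- c(msg, "riseWidth must be > 0")
  if (!length(msg) && object@t0True < 1 &&
      object@t0True + object@riseWidth > 1 + 1e-12)
    msg <- c(msg, "t0True + riseWidth must be <= 1")
  if (!one(object@plateauFraction) || object@plateauFraction <= 0 ||
      object@plateauFraction > 1)
    msg <- c(msg, "plateauFraction must be in (0, 1]")
  if (length(object@declineAge) != 1L ||
      (!is.na(object@declineAge) &&
       (object@declineAge <= object@t0True || object@declineAge > 1)))
    msg <- c(msg, "declineAge must be NA or in (t0True, 1]")
  if (!object@riseShape %in% c("linear", "smoothstep"))
    msg <- c(msg, "riseShape must be 'linear' or 'smoothstep'")
  if (!object@expressionLaw %in% c("volume", "constant"))
    msg <- c(msg, "expressionLaw must be 'volume' or 'constant'")
  if (!one(object@meanMolecules) || object@meanMolecules <= 0)
    msg <- c(msg, "meanMolecules must be > 0")
  if (!one(object@ringSigma) || object@ringSigma <= 0 ||
      object@ringSigma >= 0.4)
    msg <- c(msg, "ringSigma must be in (0, 0.4) um")
  if (!one(object@noiseCv) || object@noiseCv < 0)
    msg <- c(msg, "noiseCv must be >= 0")
  if (length(object@countingNoise) != 1L || is.na(object@countingNoise))
    msg <- c(msg, "countingNoise must be TRUE or FALSE")
  if (!one(object@photonGain) || object@photonGain <= 0)
    msg <- c(msg, "photonGain must be > 0")
  if (length(msg)) msg else TRUE
})

#' BinnedCurve: an age-binned summary curve
#'
#' Per-cell values (FCPlus, concentration, molecules, or a normalized
#' quantity) averaged in fixed-width division-cycle age classes, with a
#' two-sided Student-t confidence half-width and the occupancy of each
#' bin. Bins partition `[0, 1]`; the last bin is closed so that age 1 is
#' kept. Empty bins carry `NA` means, never 0.
#'
#' @slot binCenters Bin-center ages (e.g. 0.025, 0.075, ... for 5% bins).
#' @slot mean Per-bin mean value; `NA` for empty bins.
#' @slot ciHalfwidth Per-bin CI half-width (0 when n = 1, `NA` when
#'   n = 0).
#' @slot count Cells per bin; sums to the number of input cells.
#' @slot valueKind One of `"fcplus"`, `"concentration"`, `"molecules"`,
#'   `"normalized"`.
#' @slot binWidth,ciLevel The binning width (age fraction) and CI level.
#' @seealso [binByAge()], [minmaxNormalize()], [averageReplicates()],
#'   [estimateT0()].
#' @exportClass BinnedCurve
setClass("BinnedCurve",
  slots = c(binCenters = "numeric", mean = "numeric",
            ciHalfwidth = "numeric", count = "integer",
            valueKind = "character", binWidth = "numeric",
            ciLevel = "numeric")
)

setValidity("BinnedCurve", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@mean) != n || length(object@ciHalfwidth) != n ||
      length(object@count) != n)
    msg <- c(msg, "binCenters, mean, ciHalfwidth and count must align")
  if (is.unsorted(object@binCenters, strictly = TRUE))
    msg <- c(msg, "binCenters must be strictly increasing")
  if (any(object@count < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (any(!is.na(object@ciHalfwidth) & object@ciHalfwidth < 0))
    msg <- c(msg, "ciHalfwidth must be >= 0 where defined")
  if (any(is.na(object@mean) & object@count > 0L))
    msg <- c(msg, "occupied bins cannot have NA means")
  if (!object@valueKind %in%
      c("fcplus", "concentration", "molecules", "normalized"))
    msg <- c(msg, "invalid valueKind")
  if (length(object@binWidth) != 1L || object@binWidth <= 0 ||
      object@binWidth > 1)
    msg <- c(msg, "binWidth must be in (0, 1]")
  if (length(object@ciLevel) != 1L || object@ciLevel <= 0 ||
      object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Demograph: length-sorted map of axial fluorescence
#'
#' Rows are cells sorted ascending by length, columns are axial position
#' on a common grid centered at the cell midpoint at the population's
#' pixel pitch. Grid samples outside a cell's own length are `NA`
#' (absent), never 0. `halfLength` gives, per row, the cell half-length
#' in grid units (the white cell-outline of published demographs).
#'
#' @slot matrix Numeric matrix, `NA` outside each cell's outline.
#' @slot halfLength Per-row half-length in column units.
#' @slot lengths Per-row cell length, um (non-decreasing).
#' @slot pixelPitch Pixels per um of the common grid.
#' @slot normalized Logical: were profiles peak-normalized per cell?
#' @seealso [buildDemograph()], [renderDemograph()].
#' @exportClass Demograph
setClass("Demograph",
  slots = c(matrix = "matrix", halfLength = "numeric",
            lengths = "numeric", pixelPitch = "numeric",
            normalized = "logical")
)

setValidity("Demograph", function(object) {
  msg <- character()
  if (nrow(object@matrix) != length(object@halfLength) ||
      nrow(object@matrix) != length(object@lengths))
    msg <- c(msg, "one halfLength and length per matrix row required")
  if (is.unsorted(object@lengths))
    msg <- c(msg, "rows must be sorted ascending by cell length")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (length(msg)) msg else TRUE
})
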