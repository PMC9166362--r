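#' Construct a CellPopulation
#'
#' @param lengths,diameters Numeric vectors, um.
#' @param profiles A list (or [IRanges::NumericList]) of numeric axial
#'   fluorescence profiles, one per cell, sampled at `pixelPitch`.
#' @param cellIds Character identifiers; defaults to `cell_0001`, ...
#' @param constricting Logical flag per cell (default `FALSE`).
#' @param strain,replicateId,growthCondition Metadata strings.
#' @param pixelPitch Pixels per um (default 15.28, the scale at which
#'   the supported immunofluorescence pipelines sample profiles).
#' @param seed Integer seed recorded for simulated populations.
#' @param metadata Free-form list.
#' @return A validated [CellPopulation-class] object.
#' @examples
#' pop <- CellPopulation(
#'   lengths = c(2, 2.5), diameters = c(1, 1),
#'   profiles = list(rep(1, 31), rep(1, 38))
#' )
#' nCells(pop)
#' @export
CellPopulation <- function(lengths, diameters, profiles,
                           cellIds = sprintf("cell_%04d",
                                             seq_along(lengths)),
                           constricting = rep(FALSE, length(lengths)),
                           strain = "unspecified",
                           replicateId = "r1",
                           growthCondition = "unspecified",
                           pixelPitch = 15.28, seed = NULL,
                           metadata = list()) {
  cells <- S4Vectors::DataFrame(
    cell_id = as.character(cellIds),
    length_um = as.numeric(lengths),
    diameter_um = as.numeric(diameters),
    constricting = as.logical(constricting)
  )
  new("CellPopulation", cells = cells,
      profiles = IRanges::NumericList(profiles, compress = TRUE),
      strain = strain, replicateId = replicateId,
      growthCondition = growthCondition,
      pixelPitch = as.numeric(pixelPitch),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      metadata = metadata)
}

#' @rdname CellPopulation
#' @param x,object A `CellPopulation`.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellPopulation
#' @export
setMethod("nCells", "CellPopulation", function(x) nrow(x@cells))

#' @rdname CellPopulation
#' @export
setGeneric("cellLengths", function(x) standardGeneric("cellLengths"))

#' @rdname CellPopulation
#' @export
setMethod("cellLengths", "CellPopulation",
          function(x) x@cells$length_um)

#' @rdname CellPopulation
#' @export
setGeneric("cellDiameters", function(x) standardGeneric("cellDiameters"))

#' @rdname CellPopulation
#' @export
setMethod("cellDiameters", "CellPopulation",
          function(x) x@cells$diameter_um)

#' @rdname CellPopulation
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname CellPopulation
#' @export
setMethod("cellIds", "CellPopulation", function(x) x@cells$cell_id)

#' @rdname CellPopulation
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname CellPopulation
#' @export
setMethod("profiles", "CellPopulation", function(x) x@profiles)

#' @rdname CellPopulation
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname CellPopulation
#' @export
setMethod("pixelPitch", "CellPopulation", function(x) x@pixelPitch)

#' @rdname CellPopulation
#' @export
setGeneric("constricting", function(x) standardGeneric("constricting"))

#' @rdname CellPopulation
#' @export
setMethod("constricting", "CellPopulation",
          function(x) x@cells$constricting)

#' @rdname CellPopulation
#' @export
setGeneric("strain", function(x) standardGeneric("strain"))

#' @rdname CellPopulation
#' @export
setMethod("strain", "CellPopulation", function(x) x@strain)

#' @rdname CellPopulation
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname CellPopulation
#' @export
setMethod("replicateId", "CellPopulation", function(x) x@replicateId)

#' Ground-truth sidecar of a simulated population
#'
#' For populations built by [simulatePopulation()], returns the
#' per-cell ground truth (`cell_id`, `true_age`,
#' `true_midcell_fraction`, `true_total_F`) recorded at simulation
#' time; `NULL` for measured populations.
#' @param x A [CellPopulation-class].
#' @return A `data.frame` or `NULL`.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "CellPopulation",
          function(x) x@metadata$truth)

#' @rdname CellPopulation
#' @param i Index vector selecting cells.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "CellPopulation", function(x, i, j, ..., drop = FALSE) {
  truth <- x@metadata$truth
  md <- x@metadata
  if (!is.null(truth)) md$truth <- truth[i, , drop = FALSE]
  initialize(x, cells = x@cells[i, , drop = FALSE],
             profiles = x@profiles[i], metadata = md)
})

setMethod("show", "CellPopulation", function(object) {
  cat("CellPopulation with", nCells(object), "cells\n")
  cat("  strain:", object@strain,
      " replicate:", object@replicateId,
      " condition:", object@growthCondition, "\n")
  cat("  pixel pitch:", object@pixelPitch, "px/um\n")
  if (nCells(object)) {
    l <- cellLengths(object)
    cat(sprintf("  length: %.2f-%.2f um (median %.2f)\n",
                min(l), max(l), stats::median(l)))
    cat(sprintf("  constricting: %d (%.1f%%)\n",
                sum(constricting(object)),
                100 * mean(constricting(object))))
  }
  if (!is.null(object@metadata$truth))
    cat("  simulated: ground-truth sidecar attached\n")
  invisible(NULL)
})

#' @rdname CellPopulation
#' @export
setMethod("length", "CellPopulation", function(x) nCells(x))

#' @rdname BinnedCurve-class
#' @param x A `BinnedCurve`.
#' @param ... Ignored.
#' @return `as.data.frame` returns columns `bin_center`, `mean`, `ci`,
#'   `n`.
#' @export
setMethod("as.data.frame", "BinnedCurve", function(x, ...) {
  data.frame(bin_center = x@binCenters, mean = x@mean,
             ci = x@ciHalfwidth, n = x@count)
})

setMethod("show", "BinnedCurve", function(object) {
  occ <- sum(object@count > 0L)
  cat(sprintf(
    "BinnedCurve (%s): %d bins of width %.3f, %d occupied, %d cells\n",
    object@valueKind, length(object@binCenters), object@binWidth,
    occ, sum(object@count)))
  invisible(NULL)
})

setMethod("show", "GrowthLaw", function(object) {
  cat(sprintf("GrowthLaw: %s, birth length %.3g um, diameter %.3g um\n",
              object@mode, object@birthLength, object@diameter))
  invisible(NULL)
})

setMethod("show", "RecruitmentModel", function(object) {
  cat(sprintf(
    "RecruitmentModel: onset %.3g, rise %.3g (%s), plateau %.3g\n",
    object@t0True, object@riseWidth, object@riseShape,
    object@plateauFraction))
  cat(sprintf(
    "  expression %s (mean %.3g molecules), ring sigma %.3g um\n",
    object@expressionLaw, object@meanMolecules, object@ringSigma))
  cat(sprintf("  noise: cv %.3g, counting %s\n", object@noiseCv,
              if (object@countingNoise) "on" else "off"))
  invisible(NULL)
})

setMethod("show", "Demograph", function(object) {
  cat(sprintf(
    "Demograph: %d cells x %d axial samples (%.2f px/um)%s\n",
    nrow(object@matrix), ncol(object@matrix), object@pixelPitch,
    if (object@normalized) ", peak-normalized" else ""))
  invisible(NULL)
})
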