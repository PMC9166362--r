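#' Build a length-sorted demograph
#'
#' Stacks the axial fluorescence profiles of all cells, sorted
#' ascending by cell length (ties broken by cell id, so the map is
#' invariant to the input order), each centered on a common axial grid
#' at the population's native pixel pitch. Grid samples beyond a cell's
#' own length are absent (`NA`), never zero. Profiles are
#' center-aligned -- fixed immunolabeled cells carry no pole identity,
#' and the division site sits at the cell midpoint -- and are not
#' resampled: the native pitch is kept and rows padded.
#'
#' @param pop A [CellPopulation-class] with >= 2 cells.
#' @param normalizePerCell If `TRUE`, each profile is divided by its
#'   peak value before placement.
#' @return A [Demograph-class].
#' @export
buildDemograph <- function(pop, normalizePerCell = FALSE) {
  stopifnot(is(pop, "CellPopulation"))
  if (nCells(pop) < 2) stop("need at least 2 cells")
  ord <- order(cellLengths(pop), cellIds(pop))
  profs <- as.list(profiles(pop))[ord]
  ns <- lengths(profs)
  N <- max(ns)
  m <- matrix(NA_real_, nrow = length(profs), ncol = N)
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    if (normalizePerCell) {
      pk <- max(p)
      if (pk > 0) p <- p / pk
    }
    off <- floor((N - length(p)) / 2)
    m[i, (off + 1):(off + length(p))] <- p
  }
  new("Demograph", matrix = m, halfLength = ns / 2,
      lengths = cellLengths(pop)[ord], pixelPitch = pixelPitch(pop),
      normalized = isTRUE(normalizePerCell))
}

#' Render a demograph to a 16-bit grayscale raster
#'
#' Maps intensities affinely onto 0..65535
#' (`round((x - lo) / (hi - lo) * 65535)`), draws the cell outline (the
#' first absent sample on each side of every row) at the maximum value,
#' and renders absent samples as background 0. Passing the same
#' `sharedScale` to several demographs applies the identical mapping,
#' making rasters of different conditions directly comparable. With the
#' default per-demograph scale (the in-outline intensity range) no
#' value is clipped.
#'
#' @param d A [Demograph-class].
#' @param sharedScale Optional `c(lo, hi)` intensity mapping; values
#'   outside are clipped.
#' @return An integer matrix in 0..65535.
#' @seealso [writeDemograph()]
#' @export
renderDemograph <- function(d, sharedScale = NULL) {
  stopifnot(is(d, "Demograph"))
  vals <- d@matrix
  if (is.null(sharedScale)) {
    sharedScale <- range(vals, na.rm = TRUE)
    if (diff(sharedScale) == 0)
      sharedScale <- sharedScale + c(0, 1)
  }
  lo <- sharedScale[1]; hi <- sharedScale[2]
  if (lo >= hi) stop("invalid intensity scale: lo must be < hi")
  img <- round((pmin(pmax(vals, lo), hi) - lo) / (hi - lo) * 65535)
  img[is.na(img)] <- 0L
  nc <- ncol(img)
  center <- (nc + 1) / 2
  for (i in seq_len(nrow(img))) {
    edges <- round(c(center - d@halfLength[i] - 1,
                     center + d@halfLength[i] + 1))
    edges <- edges[edges >= 1 & edges <= nc]
    img[i, edges] <- 65535L
  }
  storage.mode(img) <- "integer"
  img
}

#' Export a demograph
#'
#' `tiff` and `png` write the [renderDemograph()] raster as 16-bit
#' grayscale; `csv` writes the raw matrix with `NA` as the
#' absent-sample sentinel.
#'
#' @param d A [Demograph-class].
#' @param path Output file.
#' @param format `"tiff"`, `"png"` or `"csv"` (default by extension).
#' @param sharedScale Passed to [renderDemograph()].
#' @return `path`, invisibly.
#' @export
writeDemograph <- function(d, path,
                           format = c("auto", "tiff", "png", "csv"),
                           sharedScale = NULL) {
  stopifnot(is(d, "Demograph"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     tif = "tiff", tiff = "tiff", png = "png", "csv")
  if (format == "csv") {
    data.table::fwrite(data.table::as.data.table(d@matrix), path,
                       na = "NA")
  } else {
    img <- renderDemograph(d, sharedScale) / 65535
    if (format == "tiff")
      tiff::writeTIFF(img, path, bits.per.sample = 16L)
    else png::writePNG(img, path)
  }
  invisible(path)
}
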