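#' Paired per-cell pixel intensities
#'
#' The unit of analysis: two vectors of pixel intensities measured for the
#' same cell (or organism) in two channels, pixel-for-pixel aligned. All
#' metrics in the package operate on this container.
#'
#' @param signal1,signal2 Numeric vectors of nonnegative, finite intensities
#'   (arbitrary units), one value per pixel, equal length >= 2.
#' @param cell_id Identifier carried through metric tables.
#' @return An object of class `cell_pixels`: a list with `signal1`,
#'   `signal2`, `cell_id` and `n_pixels`.
#' @examples
#' cell <- cell_pixels(runif(100), runif(100), "demo")
#' cell$n_pixels
#' @export
cell_pixels <- function(signal1, signal2, cell_id = "cell") {
  signal1 <- as.numeric(signal1)
  signal2 <- as.numeric(signal2)
  if (length(signal1) != length(signal2))
    tos_abort("signal1 and signal2 must have the same length", "invalid_input")
  if (length(signal1) < 2L)
    tos_abort("a cell needs at least 2 pixels", "degenerate_cell")
  if (!all(is.finite(signal1)) || !all(is.finite(signal2)))
    tos_abort("intensities must be finite", "invalid_input")
  if (any(signal1 < 0) || any(signal2 < 0))
    tos_abort("intensities must be nonnegative", "invalid_input")
  structure(list(signal1 = signal1, signal2 = signal2,
                 cell_id = as.character(cell_id)[1L],
                 n_pixels = length(signal1)),
            class = "cell_pixels")
}

#' @export
print.cell_pixels <- function(x, ...) {
  cat(sprintf("<cell_pixels> %s: %d pixels\n", x$cell_id, x$n_pixels))
  cat(sprintf("  signal1: [%.4g, %.4g]  signal2: [%.4g, %.4g]\n",
              min(x$signal1), max(x$signal1), min(x$signal2), max(x$signal2)))
  invisible(x)
}

#' Write / read a cell as a two-column CSV
#'
#' Serialization used by the pipeline: one CSV per cell with columns
#' `signal1`, `signal2` (one row per pixel, order preserved).
#'
#' @param cell A [cell_pixels()] object.
#' @param path File path.
#' @return `write_cell_csv` returns `path` invisibly; `read_cell_csv`
#'   returns a `cell_pixels`.
#' @export
write_cell_csv <- function(cell, path) {
  stopifnot(inherits(cell, "cell_pixels"))
  utils::write.csv(data.frame(signal1 = cell$signal1, signal2 = cell$signal2),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_csv
#' @param cell_id Identifier for the loaded cell; defaults to the file name.
#' @export
read_cell_csv <- function(path, cell_id = NULL) {
  if (!file.exists(path)) tos_abort(paste("no such file:", path), "invalid_input")
  d <- utils::read.csv(path)
  if (!all(c("signal1", "signal2") %in% names(d)))
    tos_abort("cell CSV must have columns signal1, signal2", "invalid_input")
  if (is.null(cell_id)) cell_id <- sub("\\.csv$", "", basename(path))
  cell_pixels(d$signal1, d$signal2, cell_id)
}
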