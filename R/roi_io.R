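# ImageJ ROI (.roi / RoiSet .zip) reading and writing, polygon and
# rectangle subtypes only (the dialects hand-drawn boundary traces use).
# The binary layout is the fixed 64-byte big-endian "Iout" header followed
# by n x-coordinates then n y-coordinates as 16-bit integers relative to
# the bounding box.

IJROI_TYPE <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
                polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L)

read_one_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    tos_abort(paste("not an ImageJ ROI file:", path), "format")
  be_short <- function(off, n = 1)
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n, 2, endian = "big")
  type <- as.integer(raw[7])
  top <- be_short(8); left <- be_short(10)
  bottom <- be_short(12); right <- be_short(14)
  n <- readBin(raw[17:18], "integer", 1, 2, signed = FALSE, endian = "big")
  name <- sub("\\.roi$", "", basename(path))
  if (type == IJROI_TYPE[["rect"]]) {
    return(list(name = name, type = "rect",
                x = c(left, right, right, left),
                y = c(top, top, bottom, bottom)))
  }
  if (!type %in% c(IJROI_TYPE[["polygon"]], IJROI_TYPE[["freehand"]],
                   IJROI_TYPE[["traced"]]))
    tos_abort(sprintf("unsupported ROI subtype %d in %s (polygon/rect only)",
                      type, path), "format")
  if (n == 0) return(NULL)                    # empty polygon: caller warns
  xs <- be_short(64, n) + left
  ys <- be_short(64 + 2 * n, n) + top
  list(name = name, type = "polygon", x = xs, y = ys)
}

#' Read ImageJ ROI traces
#'
#' Accepts a single `.roi` file, a `.zip` RoiSet archive, or a directory of
#' `.roi` files. Only polygon-family (polygon, freehand, traced) and
#' rectangle subtypes are supported. Coordinates are returned 0-based in
#' image space (x = column, y = row), rectangles as their 4-corner polygon.
#' Empty polygons are skipped with a warning.
#'
#' @param path `.roi` file, `.zip` archive or directory.
#' @return List of ROIs, each a list with `name`, `type`, `x`, `y`.
#' @export
read_imagej_rois <- function(path) {
  if (!file.exists(path)) tos_abort(paste("no such file:", path), "format")
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.roi$", full.names = TRUE)
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("roiset")
    utils::unzip(path, exdir = exdir)
    list.files(exdir, pattern = "\\.roi$", full.names = TRUE, recursive = TRUE)
  } else path
  files <- sort(files)
  rois <- list()
  for (f in files) {
    r <- read_one_roi(f)
    if (is.null(r)) {
      tos_warn(paste("empty polygon skipped:", basename(f)), "empty_roi")
      next
    }
    rois[[length(rois) + 1L]] <- r
  }
  rois
}

#' Write an ImageJ ROI file
#'
#' Minimal writer used to build synthetic fixtures and round-trip tests:
#' polygon or rectangle subtypes, 0-based vertex coordinates.
#'
#' @param x,y Integer vertex coordinates (x = column, y = row).
#' @param path Output `.roi` path.
#' @param type `"polygon"` or `"rect"` (rect uses the bounding box of x, y).
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(x, y, path, type = c("polygon", "rect")) {
  type <- match.arg(type)
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(length(x) == length(y), length(x) >= 1)
  left <- min(x); top <- min(y); right <- max(x); bottom <- max(y)
  n <- if (type == "rect") 0L else length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(227L, con, 2, endian = "big")                    # version
  writeBin(as.raw(c(IJROI_TYPE[[type]], 0L)), con)          # type byte + pad
  writeBin(as.integer(c(top, left, bottom, right)), con, 2, endian = "big")
  writeBin(n, con, 2, endian = "big")
  writeBin(raw(64 - 18), con)                               # rest of header
  if (n > 0) {
    writeBin(as.integer(x - left), con, 2, endian = "big")
    writeBin(as.integer(y - top), con, 2, endian = "big")
  }
  invisible(path)
}
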