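#' Object size / background filters for cell extraction
#'
#' Mirrors the particle filters used when hand-drawn boundaries are noisy:
#' objects smaller than `min_pixels` or larger than `max_pixels` are
#' discarded (defaults 400 and 5000), and with `background_check` objects
#' whose mean intensity in *both* channels does not exceed the mean of the
#' unlabeled (non-cell) pixels are discarded as between-cell regions.
#' `min_distinct` optionally removes cells with quantized/binned data
#' (fewer distinct intensities than the floor, in either channel); 0
#' disables it.
#'
#' @param min_pixels,max_pixels Inclusive size bounds in pixels.
#' @param background_check Logical.
#' @param min_distinct Minimum distinct-intensity count per channel (0 = off).
#' @return An `object_filter_config` list.
#' @export
object_filter_config <- function(min_pixels = 400, max_pixels = 5000,
                                 background_check = FALSE, min_distinct = 0) {
  if (min_pixels >= max_pixels)
    tos_abort("min_pixels must be below max_pixels", "invalid_input")
  structure(list(min_pixels = min_pixels, max_pixels = max_pixels,
                 background_check = background_check,
                 min_distinct = min_distinct),
            class = "object_filter_config")
}

# even-odd (ray casting) point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

rasterize_polygon <- function(vx, vy, nrow, ncol) {
  # pixel (r, c), 0-based, has center (c + 0.5, r + 0.5)
  r0 <- max(0L, floor(min(vy))); r1 <- min(nrow - 1L, ceiling(max(vy)))
  c0 <- max(0L, floor(min(vx))); c1 <- min(ncol - 1L, ceiling(max(vx)))
  out <- matrix(FALSE, nrow, ncol)
  if (r1 < r0 || c1 < c0) return(out)
  rs <- r0:r1; cs <- c0:c1
  grid <- expand.grid(r = rs, c = cs)
  inside <- points_in_polygon(grid$c + 0.5, grid$r + 0.5, vx, vy)
  out[cbind(grid$r + 1L, grid$c + 1L)] <- inside
  out
}

# 4-connected component labeling of a logical matrix (flood fill)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labels[p] != 0L) next
      labels[p] <- current
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (c > 1L) p - nr, if (c < nc) p + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  labels
}

#' Build an integer count mask from ROI boundaries
#'
#' Rasterizes each polygon to a unique positive label in an integer image
#' (0 = background), the digital analogue of ImageJ's "Count Mask". Pixels
#' are assigned by even-odd containment of their centers; where polygons
#' overlap, the later-drawn polygon wins. With `invert = TRUE` the
#' boundaries are taken to outline *background* (inverted selections): the
#' union of the polygons is complemented and each connected component of
#' the complement becomes one labeled object.
#'
#' @param rois List of ROIs from [read_imagej_rois()] (or lists with `x`,
#'   `y` vertex vectors).
#' @param shape Integer `c(rows, columns)` of the target image.
#' @param invert Complement-labeling mode (see above).
#' @return Integer label matrix of dimension `shape`.
#' @export
rois_to_count_mask <- function(rois, shape, invert = FALSE) {
  stopifnot(length(shape) == 2)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  mask <- matrix(0L, nr, nc)
  label <- 0L
  for (roi in rois) {
    if (length(roi$x) < 3) {
      tos_warn("polygon with fewer than 3 vertices skipped", "empty_roi")
      next
    }
    label <- label + 1L
    hit <- rasterize_polygon(roi$x, roi$y, nr, nc)
    mask[hit] <- label
  }
  if (invert) mask <- label_components(mask == 0L)
  mask
}

#' Read a 16-bit label TIFF as a count mask
#'
#' @param path TIFF path (integer labels, 0 = background).
#' @return Integer label matrix.
#' @export
read_count_mask <- function(path) {
  m <- read_channel_image(path)
  if (any(m != round(m)) || any(m < 0))
    tos_abort(paste("count mask must contain nonnegative integers:", path),
              "format")
  mode(m) <- "integer"
  m
}

#' Extract per-cell pixel vectors from two channel images
#'
#' Applies an integer count mask to two aligned grayscale channel images
#' and returns one [cell_pixels()] per surviving label, pixels in row-major
#' order. Labels failing the size bounds are removed; with
#' `background_check`, labels whose mean intensity in both channels does
#' not exceed the mean of the unlabeled pixels (per channel) are removed;
#' with `min_distinct > 0`, cells with quantized data are removed.
#'
#' @param mask Integer label matrix (0 = background).
#' @param channel1,channel2 Numeric intensity matrices, same dimensions.
#' @param filters An [object_filter_config()].
#' @param id_prefix Prefix for generated cell ids (`<prefix>_<label>`).
#' @return List of [cell_pixels()]; empty (with a warning) when no object
#'   survives. Attribute `"n_removed"` counts filtered-out labels.
#' @export
extract_cells <- function(mask, channel1, channel2,
                          filters = object_filter_config(),
                          id_prefix = "cell") {
  if (!all(dim(mask) == dim(channel1)) || !all(dim(mask) == dim(channel2)))
    tos_abort("mask and channel images must share dimensions", "invalid_input")
  stopifnot(inherits(filters, "object_filter_config"))
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  bg1 <- bg2 <- NA_real_
  if (filters$background_check) {
    bg <- mask == 0L
    if (!any(bg))
      tos_abort("background check requested but mask has no background pixels",
                "invalid_input")
    bg1 <- mean(channel1[bg]); bg2 <- mean(channel2[bg])
  }
  nr <- nrow(mask)
  cells <- list()
  n_removed <- 0L
  for (lab in labels) {
    idx <- which(mask == lab)
    # row-major pixel order: sort by (row, column)
    idx <- idx[order((idx - 1L) %% nr, (idx - 1L) %/% nr)]
    npx <- length(idx)
    s1 <- channel1[idx]; s2 <- channel2[idx]
    keep <- npx >= filters$min_pixels && npx <= filters$max_pixels
    if (keep && filters$background_check)
      keep <- mean(s1) > bg1 || mean(s2) > bg2
    if (keep && filters$min_distinct > 0)
      keep <- length(unique(s1)) >= filters$min_distinct &&
        length(unique(s2)) >= filters$min_distinct
    if (!keep) { n_removed <- n_removed + 1L; next }
    cells[[length(cells) + 1L]] <-
      cell_pixels(s1, s2, sprintf("%s_%d", id_prefix, lab))
  }
  if (length(cells) == 0)
    tos_warn("no objects survived the filters", "empty_extraction")
  attr(cells, "n_removed") <- n_removed
  cells
}
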