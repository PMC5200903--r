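#' Select the top fraction of pixels by intensity
#'
#' Thresholds are parameterized as *selected fractions*: the proportion of a
#' cell's highest-intensity pixels retained after rank ordering, rather than
#' as raw intensity cutoffs. This makes cells with different dynamic ranges
#' and pixel counts directly comparable. The selected count is
#' `k = max(1, round(fraction * N))` with round-half-away-from-zero, capped
#' at `N - 1` so a selection never spans the whole cell (a full selection
#' forces total overlap and carries no information).
#'
#' Ties at the selection boundary are broken by ascending pixel index after
#' descending intensity, so selection is deterministic; the effective
#' fraction `k / N` is recorded so tie inflation stays visible.
#'
#' @param pixels Numeric vector of intensities for one channel.
#' @param fraction Requested selected fraction, strictly inside (0, 1).
#' @return A `threshold_selection`: `requested_fraction`, `selected_count`,
#'   `selected_indices` (into `pixels`), `effective_fraction`, `n_pixels`,
#'   and `degenerate` (TRUE when all intensities are equal, in which case
#'   the selection is by index order only).
#' @examples
#' sel <- select_top_fraction(c(5, 1, 9, 3, 7, 2, 8), 0.5)
#' sel$selected_indices  # the 4 highest-intensity pixels
#' @export
select_top_fraction <- function(pixels, fraction) {
  pixels <- as.numeric(pixels)
  n <- length(pixels)
  if (n < 2L) tos_abort("need at least 2 pixels to threshold", "degenerate_cell")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    tos_abort("selected fraction must lie strictly in (0, 1)", "invalid_fraction")
  k <- round_half_away(fraction * n)
  k <- min(max(1L, k), n - 1L)
  ord <- order(-pixels, seq_along(pixels))
  degenerate <- max(pixels) == min(pixels)
  if (degenerate)
    tos_warn("all intensities equal; selection falls back to index order",
             "degenerate_channel")
  structure(list(requested_fraction = fraction,
                 selected_count = k,
                 selected_indices = ord[seq_len(k)],
                 effective_fraction = k / n,
                 n_pixels = n,
                 degenerate = degenerate),
            class = "threshold_selection")
}

round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Observed fractional area of overlap (AO)
#'
#' `ao1` is the fraction of channel-1 selected pixels that are also selected
#' in channel 2; `ao2` is the reverse direction. Both selections must come
#' from the same cell.
#'
#' @param sel1,sel2 `threshold_selection` objects from [select_top_fraction()]
#'   applied to the two channels of one cell.
#' @return A list with `ao1`, `ao2` and the raw `overlap_count`.
#' @export
observed_overlap <- function(sel1, sel2) {
  stopifnot(inherits(sel1, "threshold_selection"),
            inherits(sel2, "threshold_selection"))
  if (sel1$n_pixels != sel2$n_pixels)
    tos_abort("selections come from cells of different sizes",
              "incompatible_selection")
  ov <- length(intersect(sel1$selected_indices, sel2$selected_indices))
  list(ao1 = ov / sel1$selected_count,
       ao2 = ov / sel2$selected_count,
       overlap_count = ov)
}

#' AO ratio: observed vs chance-expected overlap
#'
#' Under a uniform-independent null the expected `ao1` equals the selected
#' fraction of the *other* channel (`f_t2`), and symmetrically for `ao2`.
#' Dividing observed by expected gives the AO ratio: 1 at chance-level
#' overlap, > 1 when overlap exceeds chance, < 1 when it falls short. The
#' ratio is never undefined because both fractions are > 0, and the same
#' value is obtained from either direction when the selected counts are
#' exact multiples.
#'
#' @param ao1 Observed overlap fraction for channel 1.
#' @param f_t2 Selected fraction of channel 2 (the expected `ao1`).
#' @return The AO ratio, a nonnegative scalar.
#' @export
ao_ratio <- function(ao1, f_t2) {
  if (!is.finite(f_t2) || f_t2 <= 0 || f_t2 >= 1)
    tos_abort("expected fraction must lie strictly in (0, 1)", "invalid_fraction")
  ao1 / f_t2
}

#' Analytic bounds of the AO ratio
#'
#' The maximum AO ratio occurs when the smaller selection is fully contained
#' in the larger: `1 / max(f_t1, f_t2)`. The minimum depends on
#' `f_t1 + f_t2`: zero when the selections can be disjoint (sum <= 1),
#' otherwise `(f_t1 + f_t2 - 1) / (f_t1 * f_t2)` from the forced overlap.
#' Limits are [0, 1] for the minimum and [1, Inf) for the maximum.
#'
#' @param f_t1,f_t2 Selected fractions in (0, 1). Vectorized.
#' @return A list with `min` and `max`.
#' @export
ao_ratio_bounds <- function(f_t1, f_t2) {
  if (any(!is.finite(f_t1) | f_t1 <= 0 | f_t1 >= 1) ||
      any(!is.finite(f_t2) | f_t2 <= 0 | f_t2 >= 1))
    tos_abort("selected fractions must lie strictly in (0, 1)", "invalid_fraction")
  list(min = pmax(0, (f_t1 + f_t2 - 1) / (f_t1 * f_t2)),
       max = 1 / pmax(f_t1, f_t2))
}

#' Threshold overlap score (TOS)
#'
#' Linearly rescales an AO ratio so that, at every fraction pair, the
#' analytic minimum maps to -1, the null value 1 maps to 0 and the analytic
#' maximum maps to +1. The map is piecewise linear about the null:
#' `(r - 1) / (max - 1)` above 1 and `(r - 1) / (1 - min)` below, so scores
#' are directly comparable across thresholds; e.g. TOS = 0.9 sits nine
#' tenths of the way from chance-level overlap to the maximum possible.
#'
#' @param ao_ratio_value AO ratio (see [ao_ratio()]). Vectorized.
#' @param f_t1,f_t2 The selected fractions the ratio was computed at.
#' @return TOS in [-1, 1].
#' @export
tos <- function(ao_ratio_value, f_t1, f_t2) {
  b <- ao_ratio_bounds(f_t1, f_t2)
  if (any(b$max <= 1 + 1e-12))
    tos_abort("maximum AO ratio is 1; fractions must be < 1", "invalid_fraction")
  r <- ao_ratio_value
  tol <- 1e-8 * pmax(1, b$max)
  if (any(r < b$min - tol) || any(r > b$max + tol))
    tos_abort("AO ratio outside its analytic bounds for these fractions",
              "invalid_input")
  r <- pmin(pmax(r, b$min), b$max)  # absorb float fuzz only
  ifelse(r >= 1, (r - 1) / (b$max - 1), (r - 1) / (1 - b$min))
}

#' TOS matrix over a grid of selected-fraction combinations
#'
#' Computes TOS at every combination of selected fractions for the two
#' channels (default 0.9 to 0.1 in steps of 0.1, i.e. 81 combinations; a
#' fraction of 1 is excluded because total selection forces total overlap).
#' `values[i, j]` holds TOS at `F_T1 = fractions[j]`, `F_T2 = fractions[i]`.
#' Three features are extracted: `tos_h`, the score at the lowest fraction
#' pair (the highest thresholds, where on-target signal dominates);
#' `tos_max` and `tos_min`, the grid extrema, which locate the thresholds of
#' strongest colocalization and anti-colocalization.
#'
#' Internally, observed overlap counts are normalized by the *effective*
#' fractions k/N, which makes the analytic bounds exactly attainable for
#' every integer overlap count; entries are therefore exact in [-1, 1]
#' without clamping.
#'
#' @param cell A [cell_pixels()] object.
#' @param fractions Ordered vector of selected fractions (each in (0, 1)).
#' @return A `tos_matrix`: `fractions`, `values` (matrix with `f_t2` rows and
#'   `f_t1` columns), `tos_h`, `tos_max`, `tos_min`, `cell_id`, `degenerate`.
#' @examples
#' set.seed(1)
#' m <- tos_matrix(simulate_uniform_cell(500, seed = 1))
#' round(m$tos_h, 2)
#' @export
tos_matrix <- function(cell, fractions = seq(0.9, 0.1, by = -0.1)) {
  stopifnot(inherits(cell, "cell_pixels"))
  if (any(fractions <= 0 | fractions >= 1))
    tos_abort("grid fractions must lie strictly in (0, 1)", "invalid_fraction")
  n <- cell$n_pixels
  nf <- length(fractions)
  # rank position of each pixel per channel: 1 = most intense, ties by index
  pos1 <- order(order(-cell$signal1, seq_len(n)))
  pos2 <- order(order(-cell$signal2, seq_len(n)))
  ks <- pmin(pmax(1L, round_half_away(fractions * n)), n - 1L)
  vals <- matrix(NA_real_, nf, nf,
                 dimnames = list(f_t2 = format(fractions), f_t1 = format(fractions)))
  for (i in seq_len(nf)) {        # rows: F_T2
    in2 <- pos2 <= ks[i]
    for (j in seq_len(nf)) {      # cols: F_T1
      ov <- sum(pos1 <= ks[j] & in2)
      r <- ov * n / (ks[j] * ks[i])
      vals[i, j] <- tos(r, ks[j] / n, ks[i] / n)
    }
  }
  i_low <- which.min(fractions)   # lowest fraction = highest threshold
  degenerate <- c(signal1 = max(cell$signal1) == min(cell$signal1),
                  signal2 = max(cell$signal2) == min(cell$signal2))
  structure(list(fractions = fractions, values = vals,
                 tos_h = vals[i_low, i_low],
                 tos_max = max(vals), tos_min = min(vals),
                 cell_id = cell$cell_id, degenerate = degenerate),
            class = "tos_matrix")
}

#' @export
print.tos_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<tos_matrix> %s: %dx%d grid\n", x$cell_id,
              nrow(x$values), ncol(x$values)))
  print(round(x$values, digits))
  cat(sprintf("tos_h = %.3f  tos_max = %.3f  tos_min = %.3f\n",
              x$tos_h, x$tos_max, x$tos_min))
  invisible(x)
}

#' Categorize a score as colocalization / anti-colocalization / none
#'
#' A band around zero is treated as non-colocalization so that true
#' chance-level patterns are not flip-flopped between "weak colocalization"
#' and "weak anti-colocalization" by measurement noise. The band is closed:
#' a score exactly at +/- band is non-colocalization.
#'
#' @param score Numeric vector of TOS (or TOS-like) scores.
#' @param band Half-width of the non-colocalization band (default 0.1).
#' @return Character vector with values `"colocalization"`,
#'   `"anti-colocalization"`, `"non-colocalization"`.
#' @export
classify_localization <- function(score, band = 0.1) {
  if (!is.finite(band) || band < 0)
    tos_abort("band must be a nonnegative number", "invalid_input")
  ifelse(score > band, "colocalization",
         ifelse(score < -band, "anti-colocalization", "non-colocalization"))
}

#' Serialize a TOS matrix
#'
#' CSV: 9x9 grid with the fraction grid as header row and first column
#' (rows = `f_t2`, columns = `f_t1`). JSON: fractions, values and the three
#' extracted features.
#'
#' @param m A `tos_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tos_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "tos_matrix"))
  d <- data.frame(f_t2 = m$fractions, m$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tos_matrix_csv
#' @export
write_tos_matrix_json <- function(m, path) {
  stopifnot(inherits(m, "tos_matrix"))
  jsonlite::write_json(list(cell_id = m$cell_id, fractions = m$fractions,
                            values = unname(m$values),
                            tos_h = m$tos_h, tos_max = m$tos_max,
                            tos_min = m$tos_min),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tos_matrix_csv
#' @export
read_tos_matrix_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  fr <- d[[1]]
  vals <- as.matrix(d[, -1, drop = FALSE])
  dimnames(vals) <- list(f_t2 = format(fr), f_t1 = format(fr))
  i_low <- which.min(fr)
  structure(list(fractions = fr, values = vals,
                 tos_h = vals[i_low, i_low],
                 tos_max = max(vals), tos_min = min(vals),
                 cell_id = sub("\\.csv$", "", basename(path)),
                 degenerate = c(signal1 = NA, signal2 = NA)),
            class = "tos_matrix")
}
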