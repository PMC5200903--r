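#' Pearson and Spearman correlation of a cell's two channels
#'
#' Standard product-moment correlation of the paired pixel intensities
#' (`pearson_cc`) and the same on mid-ranks, i.e. Spearman's rank
#' correlation with average ranks for ties (`spearman_cc`). Both error when
#' a channel has zero variance (zero rank variance for Spearman), since the
#' correlation is then undefined.
#'
#' @param cell A [cell_pixels()] object.
#' @return Scalar correlation in [-1, 1].
#' @export
pearson_cc <- function(cell) {
  stopifnot(inherits(cell, "cell_pixels"))
  if (stats::sd(cell$signal1) == 0 || stats::sd(cell$signal2) == 0)
    tos_abort("correlation undefined: a channel has zero variance",
              "undefined_correlation")
  stats::cor(cell$signal1, cell$signal2)
}

#' @rdname pearson_cc
#' @export
spearman_cc <- function(cell) {
  stopifnot(inherits(cell, "cell_pixels"))
  r1 <- rank(cell$signal1)
  r2 <- rank(cell$signal2)
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    tos_abort("rank correlation undefined: a channel has zero rank variance",
              "undefined_correlation")
  stats::cor(r1, r2)
}

#' Manders colocalization coefficients with chance-corrected differences
#'
#' M1 is the summed channel-1 intensity over pixels strictly exceeding
#' *both* thresholds, divided by the summed channel-1 intensity over pixels
#' exceeding its own threshold; M2 is symmetric. Because the chance-level
#' expectation of M1 equals the fraction of pixels above the channel-2
#' threshold (and vice versa), the corrected values are
#' `m1diff = m1 - f_above2` and `m2diff = m2 - f_above1`.
#'
#' @param cell A [cell_pixels()] object.
#' @param t1,t2 Intensity thresholds for channels 1 and 2; "exceed" is
#'   strict (`>`).
#' @return A `manders_result`: `m1`, `m2`, `threshold1`, `threshold2`,
#'   `f_above1`, `f_above2`, `m1diff`, `m2diff`, `thresholding_failed`.
#' @export
manders <- function(cell, t1, t2) {
  stopifnot(inherits(cell, "cell_pixels"))
  s1 <- cell$signal1; s2 <- cell$signal2
  above1 <- s1 > t1; above2 <- s2 > t2
  if (!any(above1) || !any(above2))
    tos_abort("no pixel exceeds a threshold: Manders coefficient undefined",
              "undefined_coefficient")
  joint <- above1 & above2
  structure(list(m1 = sum(s1[joint]) / sum(s1[above1]),
                 m2 = sum(s2[joint]) / sum(s2[above2]),
                 threshold1 = t1, threshold2 = t2,
                 f_above1 = mean(above1), f_above2 = mean(above2),
                 m1diff = sum(s1[joint]) / sum(s1[above1]) - mean(above2),
                 m2diff = sum(s2[joint]) / sum(s2[above2]) - mean(above1),
                 thresholding_failed = FALSE),
            class = "manders_result")
}

#' Costes automatic threshold selection
#'
#' Fits an ordinary least-squares line `signal2 = a * signal1 + b` over all
#' pixels, then scans candidate thresholds `t1` over the distinct observed
#' channel-1 intensities from high to low with `t2 = a * t1 + b` coupled
#' along the line. At each candidate the Pearson correlation of the pixels
#' strictly below both thresholds is computed (candidates with fewer than 3
#' such pixels, or zero variance among them, are skipped) and the candidate
#' pair minimizing that below-threshold correlation is returned; ties keep
#' the highest threshold. When no candidate is evaluable, or channel 1 is
#' constant (degenerate regression), the result carries `failed = TRUE`
#' rather than raising an error.
#'
#' When the fitted slope is positive the below-threshold sets are nested
#' along the scan, and an O(n log n) prefix-sum path is used; otherwise the
#' direct scan runs.
#'
#' @param cell A [cell_pixels()] object.
#' @param below `"both"` (default): below-threshold pixels must be under
#'   both channel thresholds; `"either"`: under at least one.
#' @return A list: `t1`, `t2`, `failed`, `slope`, `intercept`,
#'   `n_candidates_evaluated`.
#' @export
costes_thresholds <- function(cell, below = c("both", "either")) {
  stopifnot(inherits(cell, "cell_pixels"))
  below <- match.arg(below)
  s1 <- cell$signal1; s2 <- cell$signal2
  failed <- list(t1 = NA_real_, t2 = NA_real_, failed = TRUE,
                 slope = NA_real_, intercept = NA_real_,
                 n_candidates_evaluated = 0L)
  if (cell$n_pixels < 3L || stats::var(s1) == 0 || stats::var(s2) == 0)
    return(failed)
  a <- stats::cov(s1, s2) / stats::var(s1)
  b <- mean(s2) - a * mean(s1)
  cand <- sort(unique(s1), decreasing = TRUE)
  if (a > 0 && below == "both") {
    res <- costes_scan_nested(s1, s2, a, b, cand)
  } else {
    res <- costes_scan_direct(s1, s2, a, b, cand, below)
  }
  if (is.na(res$t1)) return(failed)
  list(t1 = res$t1, t2 = a * res$t1 + b, failed = FALSE,
       slope = a, intercept = b, n_candidates_evaluated = res$n_eval)
}

# Nested-set fast path (slope > 0, mode "both"): a pixel is below both
# thresholds once t1 exceeds e_i = max(s1_i, (s2_i - b) / a). Sorting by e_i
# gives prefix sums from which each candidate's below-set correlation
# follows in O(1).
costes_scan_nested <- function(s1, s2, a, b, cand) {
  e <- pmax(s1, (s2 - b) / a)
  o <- order(e)
  e <- e[o]; x <- s1[o]; y <- s2[o]
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  best_cor <- Inf; best_t1 <- NA_real_; n_eval <- 0L
  ptr <- 0L
  for (t1 in sort(cand)) {              # ascending: pointer only advances
    while (ptr < length(e) && e[ptr + 1L] < t1) ptr <- ptr + 1L
    m <- ptr
    if (m < 3L) next
    vx <- m * cxx[m] - cx[m]^2
    vy <- m * cyy[m] - cy[m]^2
    if (vx <= 0 || vy <= 0) next
    r <- (m * cxy[m] - cx[m] * cy[m]) / sqrt(vx * vy)
    n_eval <- n_eval + 1L
    # <= so that among equal minima the LARGEST t1 (seen later) wins,
    # matching the high-to-low scan convention
    if (r <= best_cor) { best_cor <- r; best_t1 <- t1 }
  }
  list(t1 = best_t1, n_eval = n_eval)
}

costes_scan_direct <- function(s1, s2, a, b, cand, below) {
  best_cor <- Inf; best_t1 <- NA_real_; n_eval <- 0L
  for (t1 in cand) {                    # descending: first minimum wins
    t2 <- a * t1 + b
    sel <- if (below == "both") s1 < t1 & s2 < t2 else s1 < t1 | s2 < t2
    m <- sum(sel)
    if (m < 3L) next
    x <- s1[sel]; y <- s2[sel]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    r <- stats::cor(x, y)
    n_eval <- n_eval + 1L
    if (r < best_cor) { best_cor <- r; best_t1 <- t1 }
  }
  list(t1 = best_t1, n_eval = n_eval)
}

#' Per-cell panel of all benchmarked metrics
#'
#' Computes the TOS-matrix features alongside Pearson, Spearman and the
#' Manders coefficients under Costes-selected thresholds for one cell.
#' Metrics that are undefined for the cell (failed Costes thresholding,
#' zero-variance channels) are reported as `NA` rather than erroring, so
#' panels can be assembled over heterogeneous cohorts; the paper-style
#' bookkeeping of exclusions happens downstream.
#'
#' @param cell A [cell_pixels()] object.
#' @param fractions Fraction grid passed to [tos_matrix()].
#' @return A one-row `data.frame`: `cell_id`, `tos_h`, `tos_max`, `tos_min`,
#'   `pcc`, `srcc`, `m1`, `m2`, `m1diff`, `m2diff`, `costes_failed`.
#' @export
metric_panel <- function(cell, fractions = seq(0.9, 0.1, by = -0.1)) {
  stopifnot(inherits(cell, "cell_pixels"))
  m <- tos_matrix(cell, fractions)
  pcc <- tryCatch(pearson_cc(cell), toscore_undefined_correlation = function(e) NA_real_)
  srcc <- tryCatch(spearman_cc(cell), toscore_undefined_correlation = function(e) NA_real_)
  ct <- costes_thresholds(cell)
  if (ct$failed) {
    man <- list(m1 = NA_real_, m2 = NA_real_, m1diff = NA_real_, m2diff = NA_real_)
  } else {
    man <- tryCatch(manders(cell, ct$t1, ct$t2),
                    toscore_undefined_coefficient = function(e)
                      list(m1 = NA_real_, m2 = NA_real_,
                           m1diff = NA_real_, m2diff = NA_real_))
  }
  data.frame(cell_id = cell$cell_id,
             tos_h = m$tos_h, tos_max = m$tos_max, tos_min = m$tos_min,
             pcc = pcc, srcc = srcc,
             m1 = man$m1, m2 = man$m2,
             m1diff = man$m1diff, m2diff = man$m2diff,
             costes_failed = ct$failed,
             stringsAsFactors = FALSE)
}
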