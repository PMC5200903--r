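#' Uniform-null synthetic cell
#'
#' Two channels of independent, uniformly distributed pixel intensities:
#' the null world in which observed overlap equals its expectation at every
#' threshold, so the AO ratio is ~1 and TOS ~0 over the whole matrix.
#'
#' @param n_pixels Number of pixels (default 500, the grid-calibration size).
#' @param seed Optional integer seed; the same seed reproduces the cell.
#' @param cell_id Identifier.
#' @return A [cell_pixels()] object.
#' @export
simulate_uniform_cell <- function(n_pixels = 500, seed = NULL, cell_id = "uniform") {
  if (n_pixels < 2) tos_abort("need at least 2 pixels", "degenerate_cell")
  if (!is.null(seed)) set.seed(seed)
  cell_pixels(stats::runif(n_pixels, 0, 1e4), stats::runif(n_pixels, 0, 1e4),
              cell_id)
}

#' Configuration for two-population mixture cells
#'
#' Describes a cell built from two equal-sized pixel subpopulations with
#' additive uniform noise. Population 1 carries the correlation structure
#' under study (positive / none / negative between the channels);
#' population 2 is always uncorrelated. One population's mean is stepped
#' down from `mean_start` to `mean_end` in `n_increments` equal steps, so
#' the mixture sweeps from fully overlapping populations to well-separated
#' "off-target below on-target" layouts.
#'
#' @param n_per_population Pixels per subpopulation (default 300).
#' @param noise_range Two-element range of the additive uniform deviate in
#'   arbitrary units (default `c(0, 1e4)`).
#' @param pop1_correlation `"positive"`, `"none"` or `"negative"`.
#' @param mean_start,mean_end Shifted population's mean at increment 0 and
#'   at increment `n_increments` (defaults 6.5e4 and 2.5e4 a.u.).
#' @param n_increments Number of equal mean-shift steps (default 40).
#' @param shifted_population Which population (1 or 2) moves.
#' @return A `two_population_config` list.
#' @export
two_population_config <- function(n_per_population = 300,
                                  noise_range = c(0, 1e4),
                                  pop1_correlation = c("positive", "none", "negative"),
                                  mean_start = 6.5e4, mean_end = 2.5e4,
                                  n_increments = 40,
                                  shifted_population = 2) {
  pop1_correlation <- match.arg(pop1_correlation)
  if (mean_end >= mean_start)
    tos_abort("mean_end must be below mean_start", "invalid_input")
  if (n_increments < 1) tos_abort("n_increments must be >= 1", "invalid_input")
  if (!shifted_population %in% c(1, 2))
    tos_abort("shifted_population must be 1 or 2", "invalid_input")
  structure(list(n_per_population = n_per_population, noise_range = noise_range,
                 pop1_correlation = pop1_correlation,
                 mean_start = mean_start, mean_end = mean_end,
                 n_increments = n_increments,
                 shifted_population = shifted_population),
            class = "two_population_config")
}

# correlated channel pair from a population mean and uniform deviates
pair_with_correlation <- function(n, mean, span, correlation) {
  u <- stats::runif(n, 0, span)
  switch(correlation,
         positive = list(s1 = mean + u, s2 = mean + u),
         negative = list(s1 = mean + u, s2 = mean + (span - u)),
         none = list(s1 = mean + u, s2 = mean + stats::runif(n, 0, span)))
}

#' Simulate one two-population mixture cell
#'
#' @param config A [two_population_config()].
#' @param increment Integer in `0..n_increments`: how many steps the shifted
#'   population's mean has moved from `mean_start` toward `mean_end`.
#' @param seed Optional integer seed.
#' @param cell_id Identifier.
#' @return A [cell_pixels()] object. The attribute `"distance"` records the
#'   signed mean separation: positive when population 1 was shifted down,
#'   negative when population 2 was.
#' @export
simulate_two_population_cell <- function(config, increment, seed = NULL,
                                         cell_id = "two_pop") {
  stopifnot(inherits(config, "two_population_config"))
  if (increment < 0 || increment > config$n_increments)
    tos_abort("increment out of range", "invalid_input")
  if (!is.null(seed)) set.seed(seed)
  span <- diff(range(config$noise_range))
  step <- (config$mean_start - config$mean_end) / config$n_increments
  shifted_mean <- config$mean_start - increment * step
  m1 <- if (config$shifted_population == 1) shifted_mean else config$mean_start
  m2 <- if (config$shifted_population == 2) shifted_mean else config$mean_start
  p1 <- pair_with_correlation(config$n_per_population, m1, span,
                              config$pop1_correlation)
  p2 <- pair_with_correlation(config$n_per_population, m2, span, "none")
  cell <- cell_pixels(c(p1$s1, p2$s1), c(p1$s2, p2$s2), cell_id)
  attr(cell, "distance") <- (if (config$shifted_population == 1) 1 else -1) *
    increment * step
  cell
}

#' Configuration for condition-positive / condition-negative cells
#'
#' Each cell mixes equal numbers of off-target and on-target pixels. The
#' off-target signal is positively correlated between channels with slope
#' `theta = exp(q)` (a hard-to-threshold confounder). The on-target signal
#' is positively correlated in condition-positive cells and anticorrelated
#' in condition-negative cells. Every intensity is then multiplied by an
#' independent Gaussian factor (mean 1, sd `noise_sigma`) per channel and
#' pixel.
#'
#' @param condition `"positive"` or `"negative"`.
#' @param q Log-slope of the off-target line, in `[-0.7, 0.7]`.
#' @param n_pixels Total pixels per cell (even; default 600, half per
#'   component).
#' @param off_mean,on_mean Component mean intensities (20000 and 30000 a.u.).
#' @param noise_sigma SD of the multiplicative Gaussian noise (default 0.2).
#' @param base_halfspan Half-width of the uniform spread of base intensities
#'   around each component mean (default 5000 a.u.).
#' @param recenter_off When TRUE the off-target line is pivoted about
#'   `off_mean` so both channel means stay at `off_mean` for every slope;
#'   default FALSE (channel 2 is simply `theta * channel 1`).
#' @return A `condition_config` list with `theta = exp(q)` precomputed.
#' @export
condition_config <- function(condition = c("positive", "negative"), q = 0,
                             n_pixels = 600, off_mean = 2e4, on_mean = 3e4,
                             noise_sigma = 0.2, base_halfspan = 5000,
                             recenter_off = FALSE) {
  condition <- match.arg(condition)
  if (abs(q) > 0.7 + 1e-12)
    tos_abort("q must lie in [-0.7, 0.7]", "invalid_input")
  if (n_pixels %% 2 != 0 || n_pixels < 4)
    tos_abort("n_pixels must be even and >= 4", "invalid_input")
  structure(list(condition = condition, q = q, theta = exp(q),
                 n_pixels = n_pixels, off_mean = off_mean, on_mean = on_mean,
                 noise_sigma = noise_sigma, base_halfspan = base_halfspan,
                 recenter_off = recenter_off),
            class = "condition_config")
}

#' Simulate one condition-positive or condition-negative cell
#'
#' @param config A [condition_config()].
#' @param seed Optional integer seed.
#' @param cell_id Identifier.
#' @return A [cell_pixels()] object; attribute `"n_clamped"` counts values
#'   clamped at zero after noise (a warning is raised if any).
#' @export
simulate_condition_cell <- function(config, seed = NULL, cell_id = NULL) {
  stopifnot(inherits(config, "condition_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cell_id)) cell_id <- paste0("cond_", config$condition)
  half <- config$n_pixels %/% 2
  hs <- config$base_halfspan
  # off-target: positively correlated line with slope theta
  b_off <- stats::runif(half, config$off_mean - hs, config$off_mean + hs)
  off1 <- b_off
  off2 <- if (config$recenter_off)
    config$theta * (b_off - config$off_mean) + config$off_mean
  else config$theta * b_off
  # on-target: shared base (positive) or mirrored about the mean (negative)
  b_on <- stats::runif(half, config$on_mean - hs, config$on_mean + hs)
  on1 <- b_on
  on2 <- if (config$condition == "positive") b_on else 2 * config$on_mean - b_on
  s1 <- c(off1, on1); s2 <- c(off2, on2)
  if (config$noise_sigma > 0) {
    s1 <- s1 * stats::rnorm(length(s1), 1, config$noise_sigma)
    s2 <- s2 * stats::rnorm(length(s2), 1, config$noise_sigma)
  }
  n_clamped <- sum(s1 < 0) + sum(s2 < 0)
  if (n_clamped > 0) {
    tos_warn(sprintf("%d intensities clamped at zero after noise", n_clamped),
             "clamped_intensities")
    s1 <- pmax(s1, 0); s2 <- pmax(s2, 0)
  }
  cell <- cell_pixels(s1, s2, cell_id)
  attr(cell, "n_clamped") <- n_clamped
  cell
}

#' Sweep of condition populations over a range of off-target slopes
#'
#' Generates the full ROC benchmark populations: `n_slopes` equally spaced
#' log-slopes `q` spanning `[-0.7, 0.7]`, with `cells_per_slope` cells per
#' slope per condition (defaults 141 x 50 = 7050 cells per condition). One
#' global seed spawns an independent per-cell substream so the sweep is
#' reproducible and order-independent.
#'
#' @param n_slopes Number of q increments (default 141).
#' @param cells_per_slope Cells per slope per condition (default 50).
#' @param seed Global integer seed.
#' @param conditions Which condition populations to generate.
#' @param ... Further arguments passed to [condition_config()] (e.g.
#'   `n_pixels`).
#' @return A named list (one element per condition) of lists of
#'   [cell_pixels()]; each cell carries attributes `"q"` and `"theta"`.
#' @export
sweep_conditions <- function(n_slopes = 141, cells_per_slope = 50, seed = 1,
                             conditions = c("positive", "negative"), ...) {
  if (n_slopes < 1 || cells_per_slope < 1)
    tos_abort("counts must be >= 1", "invalid_input")
  qs <- if (n_slopes == 1) 0 else seq(-0.7, 0.7, length.out = n_slopes)
  set.seed(seed)
  n_total <- n_slopes * cells_per_slope * length(conditions)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  out <- stats::setNames(vector("list", length(conditions)), conditions)
  idx <- 0L
  for (cond in conditions) {
    cells <- vector("list", n_slopes * cells_per_slope)
    k <- 0L
    for (q in qs) {
      cfg <- condition_config(condition = cond, q = q, ...)
      for (r in seq_len(cells_per_slope)) {
        idx <- idx + 1L; k <- k + 1L
        cell <- simulate_condition_cell(cfg, seed = cell_seeds[idx],
                                        cell_id = sprintf("%s_q%.4f_%03d", cond, q, r))
        attr(cell, "q") <- q
        attr(cell, "theta") <- exp(q)
        cells[[k]] <- cell
      }
    }
    out[[cond]] <- cells
  }
  attr(out, "q_values") <- qs
  attr(out, "seed") <- seed
  out
}
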