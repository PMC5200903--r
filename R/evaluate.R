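#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small problems
#' (combined n <= `exact_limit`, default 16) the null distribution of U is
#' enumerated exactly over all assignments of the observed values to groups
#' (ties included naturally); otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used. The
#' two-tailed p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))` in the
#' exact branch.
#'
#' @param values_a,values_b Numeric samples, each nonempty.
#' @param exact_limit Maximum combined sample size for exact enumeration.
#' @return A list: `u` (the U statistic for sample a), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(values_a, values_b, exact_limit = 16) {
  if (length(values_a) == 0 || length(values_b) == 0)
    tos_abort("both samples must be nonempty", "invalid_input")
  n1 <- length(values_a); n2 <- length(values_b); n <- n1 + n2
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)                      # midranks for ties
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    list(u = u, p_value = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(u = u, p_value = 1, method = "normal_approx"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(u = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_approx")
  }
}

#' Histogram bin edges for metric distributions
#'
#' Three conventions used when turning metric values into histograms and
#' ROC thresholds: `scott_sim` covers the fixed range [-1.2, 1.2] with bins
#' of Scott's-rule width `h = 3.49 * sd * n^(-1/3)` (simulated data);
#' `experimental_coarse` and `experimental_fine` use fixed increments of
#' 0.1 and 0.001 over the same range (experimental data; coarse for the
#' [-1, 1]-scaled metrics, fine for the Manders family).
#'
#' @param values Numeric vector the Scott width is estimated from (ignored
#'   by the fixed modes except for the nonempty check).
#' @param mode One of `"scott_sim"`, `"experimental_coarse"`,
#'   `"experimental_fine"`.
#' @param range_limits Range covered by the edges (default `c(-1.2, 1.2)`).
#' @return Increasing numeric vector of bin edges.
#' @export
histogram_edges <- function(values,
                            mode = c("scott_sim", "experimental_coarse",
                                     "experimental_fine"),
                            range_limits = c(-1.2, 1.2)) {
  mode <- match.arg(mode)
  if (length(values) == 0) tos_abort("values must be nonempty", "invalid_input")
  span <- diff(range_limits)
  if (mode == "experimental_coarse")
    return(seq(range_limits[1], range_limits[2], by = 0.1))
  if (mode == "experimental_fine")
    return(seq(range_limits[1], range_limits[2], by = 0.001))
  h <- 3.49 * stats::sd(values) * length(values)^(-1 / 3)
  if (!is.finite(h) || h <= 0) return(range_limits)  # degenerate spread: one bin
  nbins <- max(1L, ceiling(span / h))
  seq(range_limits[1], range_limits[2], length.out = nbins + 1L)
}

#' ROC curve from condition-positive and condition-negative values
#'
#' The threshold slides from the highest edge to the lowest; at each
#' threshold the true positive rate is the fraction of condition-positive
#' values strictly above it and the false positive rate the same fraction
#' of condition-negative values. Implicit (0,0) and (1,1) endpoints are
#' included and the AUC is the trapezoidal integral of TPR over FPR.
#'
#' @param pos_values,neg_values Metric values for the condition-positive and
#'   condition-negative populations.
#' @param edges Threshold list (typically from [histogram_edges()]).
#' @param metric_name Label carried in the result.
#' @return A `roc_result`: `thresholds` (descending), `fpr`, `tpr`, `auc`,
#'   `metric_name`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pos_values, neg_values, edges, metric_name = "metric") {
  if (length(pos_values) == 0 || length(neg_values) == 0)
    tos_abort("both populations must be nonempty", "invalid_input")
  thr <- sort(unique(edges), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_values > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_values > t), numeric(1))
  fpr_c <- c(0, fpr, 1); tpr_c <- c(0, tpr, 1)
  auc <- sum(diff(fpr_c) * (utils::head(tpr_c, -1) + utils::tail(tpr_c, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 metric_name = metric_name,
                 n_pos = length(pos_values), n_neg = length(neg_values)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC = %.3f (%d pos, %d neg, %d thresholds)\n",
              x$metric_name, x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' ROC comparison of all metrics in a panel
#'
#' Builds one ROC curve per metric column from per-cell metric panels of a
#' condition-positive and a condition-negative cohort. Cells with an
#' undefined value (e.g. `m1diff`/`m2diff` after failed Costes
#' thresholding) are dropped per metric, mirroring the exclusion
#' bookkeeping of the benchmark; a metric undefined for every cell is
#' skipped with a warning.
#'
#' @param panel_pos,panel_neg Data frames of per-cell metrics (rows = cells),
#'   e.g. from rbinding [metric_panel()] outputs.
#' @param metrics Metric column names to compare.
#' @param edges_mode Edge convention passed to [histogram_edges()].
#' @return Named list of `roc_result`s; attribute `"exclusions"` gives the
#'   number of excluded cells per metric.
#' @export
compare_metrics_roc <- function(panel_pos, panel_neg,
                                metrics = c("tos_h", "tos_max", "tos_min",
                                            "pcc", "srcc", "m1", "m2",
                                            "m1diff", "m2diff"),
                                edges_mode = "scott_sim") {
  metrics <- intersect(metrics, intersect(names(panel_pos), names(panel_neg)))
  out <- list()
  excl <- stats::setNames(integer(length(metrics)), metrics)
  for (m in metrics) {
    pos <- panel_pos[[m]]; neg <- panel_neg[[m]]
    excl[m] <- sum(is.na(pos)) + sum(is.na(neg))
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    if (length(pos) == 0 || length(neg) == 0) {
      tos_warn(sprintf("metric '%s' undefined for all cells; skipped", m),
               "metric_skipped")
      next
    }
    edges <- histogram_edges(c(pos, neg), edges_mode)
    out[[m]] <- roc_curve(pos, neg, edges, metric_name = m)
  }
  attr(out, "exclusions") <- excl
  out
}
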