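# Independent brute-force oracles. These deliberately avoid the package's
# code paths: explicit set intersections, full permutation enumeration,
# direct formula evaluation.

# AO / AO ratio / TOS by explicit set construction over one fraction pair
brute_overlap <- function(s1, s2, f1, f2) {
  n <- length(s1)
  k <- function(f) min(max(1L, as.integer(floor(f * n + 0.5))), n - 1L)
  top <- function(s, kk) {
    d <- data.frame(i = seq_len(n), v = s)
    d <- d[order(-d$v, d$i), ]
    d$i[seq_len(kk)]
  }
  k1 <- k(f1); k2 <- k(f2)
  a <- top(s1, k1); b <- top(s2, k2)
  ov <- sum(a %in% b)
  list(ao1 = ov / k1, ao2 = ov / k2,
       r = ov * n / (k1 * k2), k1 = k1, k2 = k2)
}

brute_tos <- function(r, f1, f2) {
  rmin <- if (f1 + f2 <= 1) 0 else (f1 + f2 - 1) / (f1 * f2)
  rmax <- 1 / max(f1, f2)
  if (r >= 1) (r - 1) / (rmax - 1) else (r - 1) / (1 - rmin)
}

# Mann-Whitney two-tailed p by full permutation enumeration of group labels
perm_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2, function(ix)
    sum(rk[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Costes: literal scan over all candidates using stats::cor
brute_costes <- function(s1, s2, below = "both") {
  a <- stats::cov(s1, s2) / stats::var(s1)
  b <- mean(s2) - a * mean(s1)
  best <- list(cor = Inf, t1 = NA_real_)
  for (t1 in sort(unique(s1), decreasing = TRUE)) {
    t2 <- a * t1 + b
    sel <- if (below == "both") s1 < t1 & s2 < t2 else s1 < t1 | s2 < t2
    if (sum(sel) < 3) next
    x <- s1[sel]; y <- s2[sel]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    r <- stats::cor(x, y)
    if (r < best$cor - 1e-12) best <- list(cor = r, t1 = t1)
  }
  best
}

# mid-rank Pearson (Spearman oracle)
brute_midrank_pearson <- function(x, y) stats::cor(rank(x), rank(y))
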