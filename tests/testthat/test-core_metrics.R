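test_that("select_top_fraction picks the right counts and pixels", {
  # 100-pixel worked example: fractions 0.5 and 0.1 select 50 and 10 pixels
  px <- simulate_uniform_cell(100, seed = 3)$signal1
  expect_equal(select_top_fraction(px, 0.5)$selected_count, 50L)
  expect_equal(select_top_fraction(px, 0.1)$selected_count, 10L)
  # 7 distinct intensities, fraction 0.5 -> k = round(3.5) = 4 largest
  v <- c(5, 1, 9, 3, 7, 2, 8)
  sel <- select_top_fraction(v, 0.5)
  expect_equal(sel$selected_count, 4L)
  expect_setequal(sel$selected_indices, order(v, decreasing = TRUE)[1:4])
  expect_equal(sel$effective_fraction, 4 / 7)
  # deterministic tie handling: descending intensity then ascending index
  sel_tie <- select_top_fraction(c(2, 2, 2, 1), 0.5)
  expect_equal(sel_tie$selected_indices, c(1L, 2L))
  # degenerate channel: index order, warning flag
  expect_warning(sd <- select_top_fraction(rep(3, 10), 0.3),
                 class = "toscore_degenerate_channel")
  expect_true(sd$degenerate)
  expect_equal(sd$selected_indices, 1:3)
  # errors
  expect_error(select_top_fraction(1:10, 1), class = "toscore_invalid_fraction")
  expect_error(select_top_fraction(1:10, 0), class = "toscore_invalid_fraction")
  expect_error(select_top_fraction(5, 0.5), class = "toscore_degenerate_cell")
})

test_that("observed overlap and AO ratio match the worked example", {
  # construct 100 pixels where top-50 of s1 and top-10 of s2 overlap in 5
  s1 <- numeric(100); s2 <- numeric(100)
  s1[1:50] <- 100 + (1:50)          # top 50 of signal 1 = pixels 1..50
  s2[46:55] <- 100 + (1:10)         # top 10 of signal 2 = pixels 46..55
  s1[51:100] <- 1:50; s2[c(1:45, 56:100)] <- sample(1:90)
  sel1 <- select_top_fraction(s1, 0.5)
  sel2 <- select_top_fraction(s2, 0.1)
  ov <- observed_overlap(sel1, sel2)
  expect_equal(ov$overlap_count, 5L)
  expect_equal(ov$ao1, 0.1)          # 5 of 50: the expected-by-chance value
  expect_equal(ov$ao2, 0.5)
  expect_equal(ao_ratio(ov$ao1, 0.1), 1)
  # identical / disjoint selections
  same <- observed_overlap(sel1, sel1)
  expect_equal(c(same$ao1, same$ao2), c(1, 1))
  s3 <- numeric(100); s3[51:100] <- 200   # top half disjoint from sel1
  ovd <- observed_overlap(sel1, select_top_fraction(s3, 0.5))
  expect_equal(c(ovd$ao1, ovd$ao2), c(0, 0))
  # mismatched cells
  expect_error(observed_overlap(sel1, select_top_fraction(1:50, 0.5)),
               class = "toscore_incompatible_selection")
  # full-overlap AO ratios: 2 at (0.5, 0.5) and 10 at (0.1, 0.1)
  expect_equal(ao_ratio(1, 0.5), 2)
  expect_equal(ao_ratio(1, 0.1), 10)
  expect_error(ao_ratio(1, 1), class = "toscore_invalid_fraction")
})

test_that("AO-ratio bounds follow the min/max geometry", {
  b <- ao_ratio_bounds(0.5, 0.5)
  expect_equal(c(b$min, b$max), c(0, 2))
  b <- ao_ratio_bounds(0.9, 0.9)
  expect_equal(b$min, 0.8 / 0.81)
  expect_equal(b$max, 1 / 0.9)
  b <- ao_ratio_bounds(0.1, 0.5)
  expect_equal(c(b$min, b$max), c(0, 2))
  # brute force over overlap counts, N = 100: achievable ratio range
  for (fs in list(c(0.1, 0.5), c(0.9, 0.9), c(0.3, 0.8))) {
    k1 <- round(fs[1] * 100); k2 <- round(fs[2] * 100)
    ovs <- max(0, k1 + k2 - 100):min(k1, k2)
    rs <- ovs * 100 / (k1 * k2)
    b <- ao_ratio_bounds(fs[1], fs[2])
    expect_equal(min(rs), b$min)
    expect_equal(max(rs), b$max)
  }
})

test_that("tos maps min/null/max to -1/0/+1 and is linear between", {
  fr <- seq(0.9, 0.1, by = -0.1)
  for (f1 in fr) for (f2 in fr) {
    b <- ao_ratio_bounds(f1, f2)
    expect_equal(tos(b$min, f1, f2), -1)
    expect_equal(tos(1, f1, f2), 0)
    expect_equal(tos(b$max, f1, f2), 1)
    # nine tenths from null to max -> 0.9
    expect_equal(tos(1 + 0.9 * (b$max - 1), f1, f2), 0.9)
  }
  # strictly increasing in r
  b <- ao_ratio_bounds(0.3, 0.6)
  rs <- seq(b$min, b$max, length.out = 50)
  expect_true(all(diff(tos(rs, 0.3, 0.6)) > 0))
  # tiny excursions clamp, gross ones error
  expect_equal(tos(b$max + 1e-12, 0.3, 0.6), 1)
  expect_error(tos(b$max + 0.5, 0.3, 0.6), class = "toscore_invalid_input")
})

test_that("tos_matrix: grid protocol, features and limit patterns", {
  cell <- simulate_uniform_cell(500, seed = 11)
  m <- tos_matrix(cell)
  expect_equal(dim(m$values), c(9, 9))
  expect_equal(m$fractions, seq(0.9, 0.1, by = -0.1))
  expect_true(all(m$values >= -1 & m$values <= 1))
  expect_equal(m$tos_h, m$values[9, 9])
  expect_equal(m$tos_max, max(m$values))
  expect_equal(m$tos_min, min(m$values))
  # identical ranks -> all +1
  c1 <- cell_pixels(1:100, exp(1:100 / 20))
  expect_true(all(tos_matrix(c1)$values == 1))
  # rank-reversed: entries with f1 + f2 <= 1 are exactly -1
  c2 <- cell_pixels(1:100, 100:1)
  m2 <- tos_matrix(c2)
  for (i in 1:9) for (j in 1:9)
    if (m2$fractions[i] + m2$fractions[j] <= 1)
      expect_equal(unname(m2$values[i, j]), -1)
})

test_that("tos_matrix properties: symmetry, rank invariance, oracle match", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(40:200, 1)
    s1 <- runif(n); s2 <- runif(n)
    m12 <- tos_matrix(cell_pixels(s1, s2))
    # channel symmetry: swapping channels transposes the matrix
    m21 <- tos_matrix(cell_pixels(s2, s1))
    expect_equal(m12$values, t(m21$values), ignore_attr = TRUE)
    # rank invariance under strictly increasing transforms
    m_tr <- tos_matrix(cell_pixels(log1p(s1) * 3, s2^3))
    expect_equal(m12$values, m_tr$values)
  }
  # brute-force oracle equivalence for small N over all fraction pairs
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    s1 <- sample(15, n, replace = TRUE)          # ties likely
    s2 <- sample(15, n, replace = TRUE)
    m <- tos_matrix(cell_pixels(s1, s2))
    fr <- m$fractions
    for (i in seq_along(fr)) for (j in seq_along(fr)) {
      o <- brute_overlap(s1, s2, fr[j], fr[i])
      expect_equal(unname(m$values[i, j]),
                   brute_tos(o$r, o$k1 / n, o$k2 / n))
    }
  }
  # Eqn 2 consistency: same ratio from either direction
  s1 <- runif(200); s2 <- runif(200)
  sel1 <- select_top_fraction(s1, 0.4)
  sel2 <- select_top_fraction(s2, 0.7)
  ov <- observed_overlap(sel1, sel2)
  expect_equal(ao_ratio(ov$ao1, sel2$effective_fraction),
               ao_ratio(ov$ao2, sel1$effective_fraction))
})

test_that("classify_localization applies a closed band", {
  expect_equal(classify_localization(0.05), "non-colocalization")
  expect_equal(classify_localization(-0.95), "anti-colocalization")
  expect_equal(classify_localization(0.1), "non-colocalization")   # boundary
  expect_equal(classify_localization(-0.1), "non-colocalization")
  expect_equal(classify_localization(0.100001), "colocalization")
  expect_equal(classify_localization(c(0.5, -0.5, 0), band = 0.2),
               c("colocalization", "anti-colocalization", "non-colocalization"))
  expect_error(classify_localization(0, band = -1),
               class = "toscore_invalid_input")
})

test_that("TOS matrix round-trips through CSV and JSON", {
  m <- tos_matrix(simulate_uniform_cell(100, seed = 5))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_tos_matrix_csv(m, csv)
  m2 <- read_tos_matrix_csv(csv)
  expect_equal(m2$values, m$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$tos_h, m$tos_h)
  write_tos_matrix_json(m, js)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$tos_h, m$tos_h)
  expect_equal(j$values, unname(m$values))
})
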