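test_that("TIFF write/read round trip is bit exact", {
  img <- matrix(c(0, 1, 2, 3, 40000, 65535, 7, 8, 9, 10, 11, 12),
                nrow = 3, byrow = TRUE)
  p <- tempfile(fileext = ".tif")
  write_channel_image(img, p, bits = 16)
  expect_equal(read_channel_image(p), img)
  # 8-bit and float paths
  img8 <- matrix(0:11, 4, 3)
  write_channel_image(img8, p, bits = 8)
  expect_equal(read_channel_image(p), img8 * 1.0)
  imgf <- matrix(runif(20) * 1000, 5, 4)
  write_channel_image(imgf, p, bits = 32)
  expect_equal(read_channel_image(p), imgf, tolerance = 1e-6)
  # errors: missing file, junk content, out-of-range values
  expect_error(read_channel_image(tempfile()), class = "toscore_format")
  junk <- tempfile(); writeBin(as.raw(1:20), junk)
  expect_error(read_channel_image(junk), class = "toscore_format")
  expect_error(write_channel_image(matrix(-1, 2, 2), p, bits = 16),
               class = "toscore_format")
})

test_that("ImageJ ROI write/read round trip and rasterization", {
  p <- tempfile(fileext = ".roi")
  write_imagej_roi(c(2, 8, 8, 2), c(1, 1, 4, 4), p)
  roi <- read_imagej_rois(p)[[1]]
  expect_equal(roi$type, "polygon")
  expect_equal(roi$x, c(2, 8, 8, 2))
  expect_equal(roi$y, c(1, 1, 4, 4))
  # rectangle subtype decodes to its 4-corner polygon
  pr <- tempfile(fileext = ".roi")
  write_imagej_roi(c(1, 3), c(2, 5), pr, type = "rect")
  roir <- read_imagej_rois(pr)[[1]]
  expect_equal(roir$type, "rect")
  expect_setequal(roir$x, c(1, 3))
  expect_setequal(roir$y, c(2, 5))
  # rectangle covering exactly 6 pixels
  m <- rois_to_count_mask(list(list(x = c(0, 3, 3, 0), y = c(0, 0, 2, 2))),
                          shape = c(5, 5))
  expect_equal(sum(m == 1), 6L)
  expect_true(all(m[1:2, 1:3] == 1))
  # two disjoint polygons get labels 1 and 2; counts match even-odd oracle
  tri <- list(x = c(10, 18, 10), y = c(2, 2, 8))
  rect <- list(x = c(1, 5, 5, 1), y = c(10, 10, 14, 14))
  m2 <- rois_to_count_mask(list(tri, rect), shape = c(20, 20))
  expect_setequal(setdiff(unique(as.vector(m2)), 0L), c(1L, 2L))
  inpoly <- function(px, py, vx, vy) {   # independent even-odd oracle
    n <- length(vx); cnt <- 0
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > py) != (vy[j] > py) &&
          px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
        cnt <- cnt + 1
      j <- i
    }
    cnt %% 2 == 1
  }
  want <- sum(sapply(0:19, function(r) sum(sapply(0:19, function(c)
    inpoly(c + 0.5, r + 0.5, tri$x, tri$y)))))
  expect_equal(sum(m2 == 1), want)
  # overlap: later polygon wins
  m3 <- rois_to_count_mask(list(list(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4)),
                                list(x = c(2, 6, 6, 2), y = c(0, 0, 4, 4))),
                           shape = c(6, 8))
  expect_equal(unname(m3[1, 3]), 2L)
  # inverted selection: complement of drawn boundaries, components labeled
  ring <- list(x = c(3, 12, 12, 3), y = c(3, 3, 12, 12))
  mi <- rois_to_count_mask(list(ring), shape = c(15, 15), invert = TRUE)
  expect_equal(sort(unique(as.vector(mi))), c(0L, 1L))   # one outside component
  expect_equal(sum(mi == 0), 9 * 9)                      # interior unlabeled
})

test_that("extract_cells applies size, background and quantization filters", {
  fix <- make_image_fixture()
  mask <- read_count_mask(fix$mask_path)
  expect_equal(mask, fix$mask)
  ch1 <- read_channel_image(fix$ch1_path)
  ch2 <- read_channel_image(fix$ch2_path)
  cells <- extract_cells(mask, ch1, ch2, object_filter_config(400, 5000))
  expect_length(cells, 2L)             # B (100 px) filtered out
  expect_equal(attr(cells, "n_removed"), 1L)
  expect_equal(vapply(cells, function(c) c$n_pixels, integer(1)), c(500L, 504L))
  # pixel identity: per-cell sums equal raw-grid sums restricted to labels
  expect_equal(sum(cells[[1]]$signal1), sum(ch1[mask == 1]))
  expect_equal(sum(cells[[2]]$signal2), sum(ch2[mask == 3]))
  # row-major order: first pixel of cell A is its top-left corner
  expect_equal(cells[[1]]$signal1[1], ch1[6, 6])
  expect_equal(cells[[1]]$signal1[2], ch1[6, 7])
  # relabeling permutes, never alters, cells
  remap <- c(0L, 3L, 1L, 2L)[mask + 1L]
  cells2 <- extract_cells(matrix(remap, nrow(mask)), ch1, ch2,
                          object_filter_config(400, 5000))
  expect_equal(sort(vapply(cells2, function(c) sum(c$signal1), numeric(1))),
               sort(vapply(cells, function(c) sum(c$signal1), numeric(1))))
  # size bounds: objects of 399 and 5001 pixels both removed at (400, 5000)
  m <- matrix(0L, 90, 90)
  m[seq_len(399)] <- 1L
  m[400:5400] <- 2L     # 5001 px
  g <- matrix(runif(8100), 90, 90)
  expect_warning(none <- extract_cells(m, g, g, object_filter_config(400, 5000)),
                 class = "toscore_empty_extraction")
  expect_length(none, 0L)
  # background filter removes dim between-cell objects
  mb <- matrix(0L, 30, 30); mb[2:11, 2:11] <- 1L; mb[15:24, 15:24] <- 2L
  c1 <- matrix(10, 30, 30); c2 <- matrix(10, 30, 30)
  c1[mb == 1] <- 100; c2[mb == 1] <- 100    # object 1 bright, object 2 = bg
  got <- extract_cells(mb, c1, c2, object_filter_config(50, 500,
                                                        background_check = TRUE))
  expect_length(got, 1L)
  expect_equal(got[[1]]$cell_id, "cell_1")
  # quantization filter: cell with 2 distinct values dropped when floor = 5
  mq <- matrix(0L, 20, 20); mq[1:10, 1:10] <- 1L
  gq <- matrix(rep(c(1, 2), 200), 20, 20)
  expect_warning(
    none2 <- extract_cells(mq, gq, gq,
                           object_filter_config(50, 500, min_distinct = 5)),
    class = "toscore_empty_extraction")
  expect_length(none2, 0L)
  expect_error(extract_cells(mb, c1, matrix(0, 2, 2)),
               class = "toscore_invalid_input")
})

test_that("ROI-derived mask matches the label-TIFF mask on the fixture", {
  fix <- make_image_fixture()
  rois <- read_imagej_rois(fix$roi_dir)
  m <- rois_to_count_mask(rois, dim(fix$mask))
  expect_equal(m > 0, fix$mask > 0)
  counts <- table(m[m > 0])
  expect_setequal(as.integer(counts), c(500L, 100L, 504L))
})
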