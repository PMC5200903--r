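# Synthetic image fixture built in code at test time (text-only deliverable:
# the binary TIFF/ROI files exist only inside tempdirs).
#
# A 60 x 80 two-channel image with three rectangular objects:
#   A: 20x25 = 500 px (passes the default 400..5000 size filter)
#   B: 10x10 = 100 px (too small)
#   C: 24x21 = 504 px (passes)
# Channel intensities are deterministic functions of position so per-cell
# sums have closed forms checked independently in the tests.
make_image_fixture <- function(dir = tempfile("imgfix")) {
  dir.create(dir)
  nr <- 60L; nc <- 80L
  ch1 <- matrix(0, nr, nc); ch2 <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ch1[r, c] <- 100 + r + 2 * c
    ch2[r, c] <- 500 - r + c
  }
  mask <- matrix(0L, nr, nc)
  mask[6:25, 6:30] <- 1L       # A: rows 6..25, cols 6..30 -> 500 px
  mask[36:45, 6:15] <- 2L      # B: 100 px
  mask[31:54, 51:71] <- 3L     # C: 504 px
  p1 <- file.path(dir, "ch1.tif"); p2 <- file.path(dir, "ch2.tif")
  pm <- file.path(dir, "mask.tif")
  write_channel_image(ch1, p1, bits = 16)
  write_channel_image(ch2, p2, bits = 16)
  write_channel_image(mask, pm, bits = 16)
  # equivalent ROI traces (0-based corner coordinates, pixel-edge convention)
  roi_dir <- file.path(dir, "rois"); dir.create(roi_dir)
  write_imagej_roi(c(5, 30, 30, 5), c(5, 5, 25, 25),
                   file.path(roi_dir, "A.roi"))
  write_imagej_roi(c(5, 15, 15, 5), c(35, 35, 45, 45),
                   file.path(roi_dir, "B.roi"))
  write_imagej_roi(c(50, 71, 71, 50), c(30, 30, 54, 54),
                   file.path(roi_dir, "C.roi"))
  list(dir = dir, ch1 = ch1, ch2 = ch2, mask = mask,
       ch1_path = p1, ch2_path = p2, mask_path = pm, roi_dir = roi_dir)
}
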