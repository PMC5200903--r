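# Minimal baseline-TIFF codec for single-plane grayscale images.
# No TIFF package ships with the supported R stack, and the pipeline only
# ever needs uncompressed grayscale planes (8/16-bit unsigned, 32-bit
# float), so a small purpose-built reader/writer is used. The reader
# handles both byte orders and multi-strip files; the writer emits
# little-endian single-strip files.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

tiff_type_size <- function(type) {
  # 1 BYTE, 2 ASCII, 3 SHORT, 4 LONG, 5 RATIONAL, ...
  c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
}

read_tiff_values <- function(raw, entry_raw, endian) {
  type <- readBin(entry_raw[3:4], "integer", 1, 2, signed = FALSE, endian = endian)
  count <- readBin(entry_raw[5:8], "integer", 1, 4, endian = endian)
  size <- tiff_type_size(type)
  total <- size * count
  src <- if (total <= 4) entry_raw[9:12] else {
    off <- readBin(entry_raw[9:12], "integer", 1, 4, endian = endian)
    raw[(off + 1):(off + total)]
  }
  if (type == 3L)
    readBin(src, "integer", count, 2, signed = FALSE, endian = endian)
  else if (type == 4L)
    readBin(src, "integer", count, 4, endian = endian)
  else if (type == 1L)
    as.integer(src[seq_len(count)])
  else
    tos_abort(sprintf("unsupported TIFF field type %d", type), "format")
}

#' Read a single-plane grayscale TIFF
#'
#' Supports uncompressed baseline TIFF, one sample per pixel, 8- or 16-bit
#' unsigned or 32-bit float, either byte order, one or more strips.
#' Anything else (compression, RGB, multiple planes) raises a format error
#' naming the path.
#'
#' @param path TIFF file path.
#' @return Numeric matrix (rows x columns) of nonnegative intensities.
#' @export
read_channel_image <- function(path) {
  if (!file.exists(path))
    tos_abort(paste("cannot read image:", path), "format")
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) tos_abort(paste("not a TIFF:", path), "format")
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    tos_abort(paste("not a TIFF:", path), "format")
  if (readBin(raw[3:4], "integer", 1, 2, endian = endian) != 42L)
    tos_abort(paste("not a TIFF:", path), "format")
  ifd_off <- readBin(raw[5:8], "integer", 1, 4, endian = endian)
  n_entries <- readBin(raw[(ifd_off + 1):(ifd_off + 2)], "integer", 1, 2,
                       signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e0 <- ifd_off + 2 + (i - 1) * 12
    entry <- raw[(e0 + 1):(e0 + 12)]
    tag <- readBin(entry[1:2], "integer", 1, 2, signed = FALSE, endian = endian)
    nm <- names(TIFF_TAGS)[match(tag, TIFF_TAGS)]
    if (!is.na(nm)) tags[[nm]] <- read_tiff_values(raw, entry, endian)
  }
  next_ifd <- readBin(raw[(ifd_off + 2 + n_entries * 12 + 1):
                          (ifd_off + 2 + n_entries * 12 + 4)],
                      "integer", 1, 4, endian = endian)
  if (next_ifd != 0L)
    tos_abort(paste("multi-plane TIFF unsupported:", path), "format")
  w <- tags$width; h <- tags$length
  if (is.null(w) || is.null(h))
    tos_abort(paste("malformed TIFF (no dimensions):", path), "format")
  if (!is.null(tags$compression) && tags$compression != 1L)
    tos_abort(paste("compressed TIFF unsupported:", path), "format")
  if (!is.null(tags$spp) && tags$spp != 1L)
    tos_abort(paste("multi-sample TIFF unsupported (grayscale only):", path),
              "format")
  bits <- if (is.null(tags$bits)) 1L else tags$bits[1]
  fmt <- if (is.null(tags$sample_format)) 1L else tags$sample_format[1]
  offs <- tags$strip_offsets
  cnts <- tags$strip_counts
  if (is.null(offs) || is.null(cnts))
    tos_abort(paste("malformed TIFF (no strip layout):", path), "format")
  data_raw <- do.call(c, lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + cnts[i])]))
  npx <- as.numeric(w) * h
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(data_raw, "double", npx, 4, endian = endian)
  } else if (fmt == 1L && bits == 16L) {
    readBin(data_raw, "integer", npx, 2, signed = FALSE, endian = endian)
  } else if (fmt == 1L && bits == 8L) {
    as.integer(data_raw[seq_len(npx)])
  } else {
    tos_abort(sprintf("unsupported TIFF pixel format (%d-bit, format %d): %s",
                      bits, fmt, path), "format")
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale matrix as a baseline TIFF
#'
#' Little-endian, single strip, one sample per pixel. `bits = 8` or `16`
#' writes unsigned integers (values are rounded and must fit the range);
#' `bits = 32` writes IEEE floats.
#'
#' @param img Numeric matrix (rows x columns).
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 (unsigned int) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(img, path, bits = 16) {
  stopifnot(is.matrix(img), bits %in% c(8, 16, 32))
  h <- nrow(img); w <- ncol(img)
  vals <- as.vector(t(img))                    # row-major pixel order
  fmt <- if (bits == 32) 3L else 1L
  if (fmt == 1L) {
    vals <- round(vals)
    if (any(vals < 0) || any(vals > 2^bits - 1))
      tos_abort(sprintf("values out of range for %d-bit unsigned TIFF", bits),
                "format")
  }
  n_tags <- 10L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_tags * 12L + 4L
  byte_count <- as.integer(length(vals) * bits / 8)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, 2, endian = "little")
  writeBin(ifd_off, con, 4, endian = "little")
  writeBin(n_tags, con, 2, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, 2, endian = "little")
    writeBin(as.integer(type), con, 2, endian = "little")
    writeBin(as.integer(count), con, 4, endian = "little")
    if (type == 3L) {                          # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, 2, endian = "little")
      writeBin(0L, con, 2, endian = "little")
    } else writeBin(as.integer(value), con, 4, endian = "little")
  }
  entry(256, 4, 1, w)                          # ImageWidth
  entry(257, 4, 1, h)                          # ImageLength
  entry(258, 3, 1, bits)                       # BitsPerSample
  entry(259, 3, 1, 1)                          # Compression = none
  entry(262, 3, 1, 1)                          # Photometric = BlackIsZero
  entry(273, 4, 1, data_off)                   # StripOffsets
  entry(277, 3, 1, 1)                          # SamplesPerPixel
  entry(278, 4, 1, h)                          # RowsPerStrip
  entry(279, 4, 1, byte_count)                 # StripByteCounts
  entry(339, 3, 1, fmt)                        # SampleFormat
  writeBin(0L, con, 4, endian = "little")      # next IFD: none
  if (fmt == 3L) writeBin(vals, con, 4, endian = "little")
  else if (bits == 16) writeBin(as.integer(vals), con, 2, endian = "little")
  else writeBin(as.raw(vals), con)
  invisible(path)
}
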