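# Minimal baseline TIFF codec (single channel, uncompressed, little-endian,
# one strip). Chamber images are exchanged as 16-bit grayscale TIFF and masks
# as 8-bit 0/255 TIFF; no TIFF package is assumed available.

tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

write_tiff_gray <- function(mat, path, bits) {
  stopifnot(is.matrix(mat))
  vmax <- 2^bits - 1
  v <- round(mat)
  if (any(v < 0 | v > vmax))
    stop("pixel values must be within [0, ", vmax, "] for ", bits,
         "-bit output")
  h <- nrow(mat); w <- ncol(mat)
  bytes_px <- bits %/% 8
  # header (8) + IFD: count (2) + 9 entries (9*12) + next offset (4)
  ifd_offset <- 8L
  n_entries <- 9L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  tags <- list(
    tiff_tag(256L, 3L, 1L, w),                 # ImageWidth
    tiff_tag(257L, 3L, 1L, h),                 # ImageLength
    tiff_tag(258L, 3L, 1L, bits),              # BitsPerSample
    tiff_tag(259L, 3L, 1L, 1L),                # Compression: none
    tiff_tag(262L, 3L, 1L, 1L),                # Photometric: BlackIsZero
    tiff_tag(273L, 4L, 1L, data_offset),       # StripOffsets
    tiff_tag(277L, 3L, 1L, 1L),                # SamplesPerPixel
    tiff_tag(278L, 3L, 1L, h),                 # RowsPerStrip
    tiff_tag(279L, 4L, 1L, w * h * bytes_px))  # StripByteCounts
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(n_entries, con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg$id, con, size = 2, endian = "little")
    writeBin(tg$type, con, size = 2, endian = "little")
    writeBin(tg$count, con, size = 4, endian = "little")
    if (tg$type == 3L) { # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(tg$value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg$value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  # pixel data, row-major
  px <- as.integer(t(v))
  if (bits == 16L) {
    px[px > 32767L] <- px[px > 32767L] - 65536L # two's complement for writeBin
    writeBin(px, con, size = 2, endian = "little")
  } else {
    writeBin(px, con, size = 1)
  }
  invisible(path)
}

read_uint <- function(raw, offset, size) {
  b <- as.integer(raw[offset + seq_len(size)])
  sum(b * 256^(seq_len(size) - 1))
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF is supported")
  if (read_uint(raw, 2, 2) != 42) stop("not a TIFF file")
  ifd <- read_uint(raw, 4, 4)
  n <- read_uint(raw, ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    at <- ifd + 2 + (i - 1) * 12
    id <- read_uint(raw, at, 2)
    type <- read_uint(raw, at + 2, 2)
    val <- if (type == 3) read_uint(raw, at + 8, 2) else
      read_uint(raw, at + 8, 4)
    tags[[as.character(id)]] <- val
  }
  need <- function(id) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) stop("missing TIFF tag ", id)
    v
  }
  w <- need(256); h <- need(257); bits <- need(258)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
    stop("compressed TIFF is not supported")
  offset <- need(273)
  bytes_px <- bits %/% 8
  npx <- w * h
  px <- numeric(npx)
  if (bits == 16) {
    for (i in seq_len(npx))
      px[i] <- read_uint(raw, offset + (i - 1) * bytes_px, 2)
  } else if (bits == 8) {
    px <- as.numeric(raw[offset + seq_len(npx)])
  } else stop("unsupported bit depth: ", bits)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' Read / write 16-bit grayscale TIFF images
#'
#' Minimal baseline TIFF support (uncompressed, little-endian, single strip,
#' one channel) for exchanging exclusion-chamber images. Values are rounded
#' to integers in `[0, 65535]`.
#'
#' @param mat Numeric matrix of intensities.
#' @param path File path.
#' @return `write_tiff16` returns the path invisibly; `read_tiff16` returns a
#'   numeric matrix.
#' @export
write_tiff16 <- function(mat, path) write_tiff_gray(mat, path, 16L)

#' @rdname write_tiff16
#' @export
read_tiff16 <- function(path) read_tiff_gray(path)

#' Read / write binary masks as 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `write_mask_tiff` returns the path invisibly; `read_mask_tiff`
#'   returns a logical matrix (pixels > 127 are `TRUE`).
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask))
  write_tiff_gray(ifelse(mask, 255, 0), path, 8L)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) read_tiff_gray(path) > 127
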