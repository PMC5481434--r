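#' Minimal grayscale TIFF input/output
#'
#' The pipeline exchanges one 2-D intensity image per channel per round as a
#' single-channel baseline TIFF (little-endian, uncompressed, one image per
#' file, 8- or 16-bit unsigned). No TIFF-capable package ships with the
#' supported toolchain, so the codec is implemented here; it covers exactly
#' the subset of the format this package writes plus multi-strip files and
#' big-endian byte order on read.
#'
#' @name tiff-io
#' @keywords internal
NULL

.tiff_tag <- function(id, type, count, value_raw, data_offset) {
  # type 3 = SHORT, 4 = LONG; values <= 4 bytes are stored inline
  list(id = id, type = type, count = count, value_raw = value_raw,
       data_offset = data_offset)
}

.u16le <- function(x) as.raw(rbind(x %% 256L, x %/% 256L))
.u32le <- function(x) {
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}

#' Write a matrix as a grayscale TIFF
#'
#' @param img integer or numeric matrix; values are rounded and clipped to
#'   the unsigned range of `bits`.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  v <- round(as.numeric(t(img)))        # row-major pixel order
  v[v < 0] <- 0
  v[v > maxval] <- maxval
  h <- nrow(img); w <- ncol(img)
  pix <- if (bits == 8L) as.raw(v) else .u16le(as.integer(v))

  data_offset <- 8L
  ifd_offset <- data_offset + length(pix)
  if (ifd_offset %% 2L == 1L) { pix <- c(pix, as.raw(0)); ifd_offset <- ifd_offset + 1L }

  short_val <- function(x) c(.u16le(as.integer(x)), as.raw(c(0, 0)))
  entries <- list(
    c(.u16le(256L), .u16le(3L), .u32le(1), short_val(w)),    # ImageWidth
    c(.u16le(257L), .u16le(3L), .u32le(1), short_val(h)),    # ImageLength
    c(.u16le(258L), .u16le(3L), .u32le(1), short_val(bits)), # BitsPerSample
    c(.u16le(259L), .u16le(3L), .u32le(1), short_val(1L)),   # Compression: none
    c(.u16le(262L), .u16le(3L), .u32le(1), short_val(1L)),   # Photometric: min-is-black
    c(.u16le(273L), .u16le(4L), .u32le(1), .u32le(data_offset)), # StripOffsets
    c(.u16le(277L), .u16le(3L), .u32le(1), short_val(1L)),   # SamplesPerPixel
    c(.u16le(278L), .u16le(3L), .u32le(1), short_val(h)),    # RowsPerStrip
    c(.u16le(279L), .u16le(4L), .u32le(1), .u32le(h * w * (bits / 8))), # StripByteCounts
    c(.u16le(339L), .u16le(3L), .u32le(1), short_val(1L))    # SampleFormat: unsigned
  )
  ifd <- c(.u16le(length(entries)), do.call(c, entries), .u32le(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .u16le(42L), .u32le(ifd_offset), pix, ifd),
           con)
  invisible(path)
}

.rd_u <- function(raw, offset, nbytes, le) {
  # read one unsigned integer of nbytes at 1-based offset
  b <- as.integer(raw[offset:(offset + nbytes - 1L)])
  if (!le) b <- rev(b)
  sum(b * 256^(seq_along(b) - 1))
}

#' Read a grayscale TIFF written by [write_tiff()] (or compatible)
#'
#' Supports uncompressed single-sample baseline TIFF, 8 or 16 bits,
#' either byte order, one or more strips; only the first image (IFD) of a
#' file is read.
#'
#' @param path file path.
#' @return integer matrix of pixel intensities.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  byte_order <- rawToChar(raw[1:2])
  le <- byte_order == "II"
  if (!le && byte_order != "MM") stop("not a TIFF file: ", path)
  if (.rd_u(raw, 3L, 2L, le) != 42) stop("not a TIFF file: ", path)
  ifd <- .rd_u(raw, 5L, 4L, le) + 1L

  n_entries <- .rd_u(raw, ifd, 2L, le)
  tags <- list()
  type_size <- c(1L, 1L, 2L, 4L, 8L)
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    id <- .rd_u(raw, e, 2L, le)
    type <- .rd_u(raw, e + 2L, 2L, le)
    count <- .rd_u(raw, e + 4L, 4L, le)
    sz <- type_size[type] * count
    voff <- if (sz <= 4) e + 8L else .rd_u(raw, e + 8L, 4L, le) + 1L
    vals <- vapply(seq_len(count), function(j)
      .rd_u(raw, voff + (j - 1L) * type_size[type], type_size[type], le), 0)
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) { if (is.null(default)) stop("missing TIFF tag ", id); default } else v
  }
  w <- need(256); h <- need(257); bits <- need(258, 8)
  if (length(bits) > 1 || !(bits %in% c(8, 16))) stop("unsupported bit depth")
  if (need(259, 1) != 1) stop("compressed TIFF not supported")
  if (need(277, 1) != 1) stop("multi-sample TIFF not supported")
  offs <- need(273); counts <- need(279, h * w * bits / 8)

  bytes <- do.call(c, lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1L):(offs[i] + counts[i])]))
  v <- if (bits == 8) as.integer(bytes) else {
    b <- matrix(as.integer(bytes), nrow = 2L)
    if (le) b[1L, ] + 256L * b[2L, ] else b[2L, ] + 256L * b[1L, ]
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}
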