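# Minimal baseline TIFF support: single-sample grayscale, uncompressed,
# 8/16-bit unsigned, 32-bit signed integer, 32-bit float; little-endian
# written, either endianness read. Deliberately small: no pyramids, no
# compression, no RGB -- whole-slide channels and label maps only.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a grayscale TIFF
#'
#' @param img numeric or integer matrix.
#' @param path output file.
#' @param format one of \code{"uint8"}, \code{"uint16"}, \code{"int32"},
#'   \code{"float32"}. Integer formats round and clamp to the valid range.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(img, path, format = c("uint16", "uint8", "int32", "float32")) {
  format <- match.arg(format)
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  bits <- switch(format, uint8 = 8L, uint16 = 16L, int32 = 32L, float32 = 32L)
  sfmt <- switch(format, uint8 = 1L, uint16 = 1L, int32 = 2L, float32 = 3L)
  bytes_px <- bits %/% 8L
  n_entries <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + 12L * n_entries + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT: value left-justified in 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256L, 4L, 1L, nc)                      # ImageWidth
  entry(257L, 4L, 1L, nr)                      # ImageLength
  entry(258L, 3L, 1L, bits)                    # BitsPerSample
  entry(259L, 3L, 1L, 1L)                      # Compression = none
  entry(262L, 3L, 1L, 1L)                      # Photometric = BlackIsZero
  entry(273L, 4L, 1L, data_offset)             # StripOffsets
  entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
  entry(278L, 4L, 1L, nr)                      # RowsPerStrip (single strip)
  entry(279L, 4L, 1L, nr * nc * bytes_px)      # StripByteCounts
  entry(339L, 3L, 1L, sfmt)                    # SampleFormat
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  v <- as.vector(t(img))                        # TIFF is row-major
  if (format == "float32") {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    lim <- switch(format, uint8 = c(0, 255), uint16 = c(0, 65535),
                  int32 = c(-2147483647, 2147483647))
    v <- pmin(pmax(round(v), lim[1]), lim[2])
    writeBin(as.integer(v), con, size = bytes_px, endian = "little")
  }
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Supports uncompressed single-sample images (8/16-bit unsigned, 32-bit
#' signed, 32-bit float), little- or big-endian, strip layout. Values are
#' returned exactly as stored: 8-bit data is \emph{not} rescaled.
#'
#' @param path TIFF file.
#' @return numeric matrix \code{[row, col]}.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF (file too short): ", path)
  con <- rawConnection(raw_all)
  on.exit(close(con))
  byte_order <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF (bad byte-order mark): ", path))
  magic <- readBin(con, "integer", 1, size = 2, endian = need <- endian)
  if (magic != 42L) stop("not a TIFF (bad magic number): ", path)
  ifd_offset <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (ifd_offset + 2 > length(raw_all)) stop("truncated TIFF: ", path)
  seek(con, ifd_offset)
  n_entries <- readBin(con, "integer", 1, size = 2, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, endian = endian, signed = FALSE)
    type <- readBin(con, "integer", 1, size = 2, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    value_field <- readBin(con, "raw", 4)
    tsize <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(tsize)) next
    nbytes <- tsize * count
    vraw <- if (nbytes <= 4) value_field[seq_len(nbytes)] else {
      off <- read_uint32(value_field, endian)
      if (off + nbytes > length(raw_all)) stop("truncated TIFF: ", path)
      raw_all[(off + 1):(off + nbytes)]
    }
    vals <- if (type == 3L) {
      readBin(vraw, "integer", count, size = 2, endian = endian, signed = FALSE)
    } else if (type %in% c(1L, 4L)) {
      readBin(vraw, "integer", count, size = tsize, endian = endian,
              signed = tsize >= 4)
    } else next
    tags[[as.character(tag)]] <- vals
  }
  need_tag <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      default
    } else v
  }
  width <- need_tag(256L); height <- need_tag(257L)
  bits <- need_tag(258L, 1L); compression <- need_tag(259L, 1L)
  spp <- need_tag(277L, 1L); sfmt <- need_tag(339L, 1L)
  if (compression != 1L) stop("unsupported TIFF compression (", compression,
                              "); only uncompressed images are supported")
  if (length(bits) > 1L || spp != 1L)
    stop("multi-channel/RGB TIFF not supported; export single-channel ",
         "grayscale images and pass one file per channel")
  if (!(bits %in% c(8L, 16L, 32L)))
    stop("unsupported bit depth: ", bits)
  strip_offsets <- need_tag(273L)
  strip_counts <- need_tag(279L)
  bytes_px <- bits %/% 8L
  expected <- as.numeric(width) * height * bytes_px
  if (sum(as.numeric(strip_counts)) < expected)
    stop("truncated TIFF (strip byte counts < image size): ", path)
  vals <- numeric(0)
  what <- if (sfmt == 3L) "numeric" else "integer"
  for (s in seq_along(strip_offsets)) {
    a <- strip_offsets[s]; nb <- strip_counts[s]
    if (a + nb > length(raw_all)) stop("truncated TIFF (strip beyond EOF): ", path)
    sraw <- raw_all[(a + 1):(a + nb)]
    n <- nb %/% bytes_px
    v <- readBin(sraw, what, n, size = bytes_px, endian = endian,
                 signed = if (what == "integer") (sfmt == 2L || bytes_px == 4L) else TRUE)
    if (sfmt == 1L && bytes_px == 4L) v[v < 0] <- v[v < 0] + 2^32
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) < width * height) stop("truncated TIFF (pixel data short): ", path)
  matrix(vals[seq_len(width * height)], nrow = height, ncol = width, byrow = TRUE)
}

read_uint32 <- function(r, endian) {
  v <- readBin(r, "integer", 1, size = 4, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}
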