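# Minimal grayscale raster codecs (PNG, TIFF).
#
# The package reads and writes single-channel 8/16-bit rasters only; palette,
# alpha or RGB inputs are rejected rather than flattened, so recorded
# decorrelation intensities are never silently transformed.  PNG support is
# non-interlaced greyscale (colour type 0) with full filter reconstruction;
# TIFF support is uncompressed, single-sample, either endianness.

PNG_SIG <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

rd_u32be <- function(raw4) {
  sum(as.numeric(raw4) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(cpp_crc32(body)))
}

#' Write a grayscale matrix as PNG
#'
#' @param pixels integer matrix (row 1 = top row of the image), values in
#'   `[0, 2^bit_depth - 1]`.
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @keywords internal
write_gray_png <- function(pixels, path, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxv))
    stop("pixel values outside [0, ", maxv, "]")
  h <- nrow(pixels); w <- ncol(pixels)
  ihdr <- c(u32be(w), u32be(h), as.raw(bit_depth), as.raw(0L),
            as.raw(0L), as.raw(0L), as.raw(0L))
  vals <- as.integer(t(pixels)) # row-major scanlines
  if (bit_depth == 8L) {
    rowbytes <- w
    bytes <- as.raw(vals)
  } else {
    rowbytes <- 2L * w
    bytes <- as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L))) # big-endian
  }
  scan <- matrix(bytes, nrow = rowbytes, ncol = h)
  filtered <- as.raw(rbind(matrix(as.raw(0L), 1L, h), scan)) # filter type 0
  idat <- memCompress(as.vector(filtered), type = "gzip")
  out <- c(PNG_SIG, png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a grayscale PNG
#'
#' @param path PNG file; must be non-interlaced grayscale (colour type 0),
#'   8- or 16-bit.
#' @return list with `pixels` (integer matrix, row 1 = top) and `bit_depth`.
#' @keywords internal
read_gray_png <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8 || !identical(raw_all[1:8], PNG_SIG))
    stop("not a PNG file: ", path)
  pos <- 9L
  idat <- list()
  hdr <- NULL
  while (pos + 8 <= length(raw_all)) {
    len <- rd_u32be(raw_all[pos:(pos + 3)])
    type <- rawToChar(raw_all[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw_all[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") hdr <- data
    if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(hdr)) stop("corrupt PNG (no IHDR): ", path)
  w <- rd_u32be(hdr[1:4]); h <- rd_u32be(hdr[5:8])
  bit_depth <- as.integer(hdr[9]); color_type <- as.integer(hdr[10])
  interlace <- as.integer(hdr[13])
  if (color_type != 0L)
    stop("unsupported PNG colour type ", color_type,
         ": only single-channel grayscale input is accepted")
  if (!bit_depth %in% c(8L, 16L))
    stop("unsupported PNG bit depth ", bit_depth, " (need 8 or 16)")
  if (interlace != 0L) stop("interlaced PNG not supported")
  comp <- memDecompress(do.call(c, idat), type = "gzip")
  bpp <- if (bit_depth == 8L) 1L else 2L
  rowbytes <- bpp * w
  bytes <- cpp_png_unfilter(comp, h, rowbytes, bpp)
  if (bit_depth == 8L) {
    vals <- as.integer(bytes)
  } else {
    m <- matrix(as.integer(bytes), nrow = 2L)
    vals <- m[1, ] * 256L + m[2, ]
  }
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       bit_depth = bit_depth)
}

# --- TIFF ------------------------------------------------------------------

tiff_entry <- function(tag, type, count, value) {
  # little-endian IFD entry; value already padded to 4 bytes
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value)
}

le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"),
                        raw(2))

#' Write a grayscale matrix as uncompressed TIFF (little-endian, single strip)
#' @inheritParams write_gray_png
#' @keywords internal
write_gray_tiff <- function(pixels, path, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxv))
    stop("pixel values outside [0, ", maxv, "]")
  h <- nrow(pixels); w <- ncol(pixels)
  vals <- as.integer(t(pixels))
  data <- if (bit_depth == 8L) as.raw(vals) else
    writeBin(vals, raw(), size = 2, endian = "little")
  strip_offset <- 8L
  ifd_offset <- 8L + length(data)
  entries <- list(
    tiff_entry(256, 4, 1, le4(w)),            # ImageWidth
    tiff_entry(257, 4, 1, le4(h)),            # ImageLength
    tiff_entry(258, 3, 1, le2pad(bit_depth)), # BitsPerSample
    tiff_entry(259, 3, 1, le2pad(1L)),        # Compression = none
    tiff_entry(262, 3, 1, le2pad(1L)),        # Photometric = BlackIsZero
    tiff_entry(273, 4, 1, le4(strip_offset)), # StripOffsets
    tiff_entry(277, 3, 1, le2pad(1L)),        # SamplesPerPixel
    tiff_entry(278, 4, 1, le4(h)),            # RowsPerStrip
    tiff_entry(279, 4, 1, le4(length(data)))  # StripByteCounts
  )
  out <- c(charToRaw("II"), writeBin(42L, raw(), size = 2, endian = "little"),
           le4(ifd_offset), data,
           writeBin(length(entries), raw(), size = 2, endian = "little"),
           do.call(c, entries), le4(0L))
  writeBin(out, path)
  invisible(path)
}

rd_int <- function(raw_all, pos, size, endian) {
  if (size <= 2) {
    as.numeric(readBin(raw_all[pos:(pos + size - 1)], "integer", size = size,
                       endian = endian, signed = FALSE))
  } else {
    v <- as.numeric(readBin(raw_all[pos:(pos + size - 1)], "integer",
                            size = size, endian = endian))
    if (v < 0) v + 2^32 else v
  }
}

#' Read an uncompressed grayscale TIFF
#' @return list with `pixels` and `bit_depth`.
#' @keywords internal
read_gray_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw_all[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (rd_int(raw_all, 3, 2, endian) != 42) stop("not a TIFF file: ", path)
  ifd <- rd_int(raw_all, 5, 4, endian) + 1
  n_entries <- rd_int(raw_all, ifd, 2, endian)
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd_int(raw_all, e, 2, endian)
    typ <- rd_int(raw_all, e + 2, 2, endian)
    cnt <- rd_int(raw_all, e + 4, 4, endian)
    if (!typ %in% c(1, 3, 4)) next # only BYTE/SHORT/LONG tags are relevant
    sz <- type_size[typ] * cnt
    vpos <- if (sz <= 4) e + 8 else rd_int(raw_all, e + 8, 4, endian) + 1
    esz <- type_size[typ]
    vals <- vapply(seq_len(cnt), function(k)
      rd_int(raw_all, vpos + (k - 1) * esz, esz, endian), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1)
  if (need(259, 1) != 1) stop("compressed TIFF not supported")
  spp <- need(277, 1)
  if (spp != 1 || length(bits) != 1)
    stop("unsupported TIFF with ", spp,
         " samples/pixel: only single-channel grayscale input is accepted")
  if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth ", bits)
  offsets <- need(273); counts <- need(279)
  data <- do.call(c, lapply(seq_along(offsets), function(k)
    raw_all[(offsets[k] + 1):(offsets[k] + counts[k])]))
  if (bits == 8) {
    vals <- as.integer(data)
  } else {
    vals <- readBin(data, "integer", n = length(data) / 2, size = 2,
                    endian = endian, signed = FALSE)
  }
  list(pixels = matrix(as.integer(vals), nrow = h, ncol = w, byrow = TRUE),
       bit_depth = as.integer(bits))
}

read_gray_raster <- function(path) {
  raw8 <- readBin(path, "raw", n = 8)
  if (length(raw8) >= 8 && identical(raw8, PNG_SIG)) return(read_gray_png(path))
  magic <- rawToChar(raw8[1:2])
  if (magic %in% c("II", "MM")) return(read_gray_tiff(path))
  stop("unrecognized raster format (need PNG or TIFF): ", path)
}

write_gray_raster <- function(pixels, path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_gray_tiff(pixels, path, bit_depth)
  else write_gray_png(pixels, path, bit_depth)
}
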