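# Minimal baseline TIFF codec (little-endian, uncompressed, single-sample
# grayscale, multi-page). No TIFF package ships with this stack, so the
# subset needed for microscopy rasters is implemented here: 16-bit unsigned
# integer and 32-bit IEEE float pages. Not a general-purpose TIFF reader.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param pages a matrix or list of numeric/integer matrices, one per page;
#'   all pages share one pixel type.
#' @param path output file.
#' @param type `"float64"` (lossless for R numerics, the default for
#'   intensity rasters), `"float32"`, or `"uint16"` for label masks (values
#'   must fit in 0..65535).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path,
                       type = c("float64", "float32", "uint16")) {
  type <- match.arg(type)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) > 0, all(vapply(pages, is.matrix, logical(1))))
  bps <- switch(type, float64 = 8L, float32 = 4L, uint16 = 2L)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)        # "II", magic 42
  writeBin(8L, con, size = 4, endian = "little")          # first IFD offset

  offset <- 8L
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    h <- nrow(m); w <- ncol(m)
    data_bytes <- w * h * bps
    data_offset <- offset + ifd_size
    next_ifd <- if (k < length(pages)) data_offset + data_bytes else 0L

    entry <- function(tag, typ, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(typ), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (typ == 3L) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                        # ImageWidth
    entry(257L, 4L, 1L, h)                        # ImageLength
    entry(258L, 3L, 1L, bps * 8L)                 # BitsPerSample
    entry(259L, 3L, 1L, 1L)                       # Compression = none
    entry(262L, 3L, 1L, 1L)                       # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_offset)              # StripOffsets
    entry(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    entry(278L, 4L, 1L, h)                        # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)               # StripByteCounts
    entry(339L, 3L, 1L, if (type == "uint16") 1L else 3L)   # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")

    v <- as.vector(t(m))  # TIFF stores rows sequentially
    if (type == "uint16") {
      v <- as.integer(round(v))
      if (any(v < 0 | v > 65535))
        stop("uint16 TIFF values must lie in 0..65535")
      v <- ifelse(v > 32767L, v - 65536L, v)  # reinterpret as signed bits
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = bps, endian = "little")
    }
    offset <- data_offset + data_bytes
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()] (or any
#' uncompressed little-endian single-sample baseline TIFF)
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) {
    sum(as.integer(raw[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(as.integer(raw[off + 1:4])) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian ('II') TIFFs are supported")
  if (u16(2) != 42L) stop("not a TIFF file")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- u16(e); typ <- u16(e + 2); cnt <- u32(e + 4)
      val_off <- e + 8
      read_vals <- function() {
        sz <- c(`1` = 1, `3` = 2, `4` = 4)[[as.character(typ)]]
        off <- if (cnt * sz > 4) u32(val_off) else val_off
        vapply(seq_len(cnt), function(j) {
          if (sz == 2) u16(off + (j - 1) * 2) else
            if (sz == 4) u32(off + (j - 1) * 4) else
              as.numeric(raw[off + j])
        }, numeric(1))
      }
      if (tag %in% TIFF_TAGS) tags[[as.character(tag)]] <- read_vals()
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop("TIFF missing dimensions")
    if (g(259L, 1) != 1) stop("compressed TIFFs are not supported")
    if (g(277L, 1) != 1) stop("multi-sample TIFFs are not supported")
    bits <- g(258L, 1)
    fmt <- g(339L, 1)
    offs <- g(273L); cnts <- g(279L, w * h * bits / 8)
    buf <- raw(0)
    for (j in seq_along(offs))
      buf <- c(buf, raw[offs[j] + seq_len(cnts[j])])
    v <- if (bits %in% c(32, 64) && fmt == 3) {
      readBin(buf, "numeric", n = w * h, size = bits / 8, endian = "little")
    } else if (bits == 16 && fmt %in% c(1, 4)) {
      x <- readBin(buf, "integer", n = w * h, size = 2, signed = FALSE,
                   endian = "little")
      as.numeric(x)
    } else if (bits == 8 && fmt %in% c(1, 4)) {
      as.numeric(as.integer(buf[seq_len(w * h)]))
    } else stop("unsupported TIFF pixel type: ", bits, " bits, format ", fmt)
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}
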