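# Minimal baseline TIFF 6.0 codec: grayscale, uncompressed, single sample per
# pixel, multi-page.  Written because no TIFF-capable R package is available
# in the supported dependency set.  Covers what fluorescence time-lapse
# exports need: uint8/uint16 counts and float32 processed stacks.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

.le_int <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

.tiff_entry <- function(tag, type, count, value) {
  # value must already fit in 4 bytes (all tags we emit do)
  val <- if (type == TIFF_TYPE_SHORT) {
    c(.le_int(value, 2L), as.raw(c(0, 0)))
  } else {
    .le_int(value, 4L)
  }
  c(.le_int(tag, 2L), .le_int(type, 2L), .le_int(count, 4L), val)
}

#' Write a grayscale multi-page TIFF
#'
#' Encodes a stack of frames as an uncompressed little-endian TIFF.  Pixel
#' type is chosen by `bits`: 32 stores IEEE float32 (sample format 3), 16 and
#' 8 store unsigned integers (values are rounded and clamped).
#'
#' @param frames 3D numeric array `[rows, cols, frames]`, or a matrix for a
#'   single page.
#' @param path output file path.
#' @param bits bits per sample: 8, 16 or 32 (default 32, float).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, bits = 32L) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, bits %in% c(8L, 16L, 32L))
  nr <- dim(frames)[1]; nc <- dim(frames)[2]; nt <- dim(frames)[3]
  bytes_px <- bits / 8L
  strip_len <- nr * nc * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  # header: II, magic 42, offset of first IFD (right after the header)
  writeBin(charToRaw("II"), con)
  writeBin(as.raw(c(0x2a, 0x00)), con)
  ifd_size <- 2L + 10L * 12L + 4L
  first_ifd <- 8L
  writeBin(.le_int(first_ifd, 4L), con)
  data_block <- first_ifd + nt * ifd_size  # all IFDs first, then pixel data
  for (t in seq_len(nt)) {
    strip_off <- data_block + (t - 1L) * strip_len
    next_ifd <- if (t < nt) first_ifd + t * ifd_size else 0L
    entries <- c(
      .tiff_entry(256L, TIFF_TYPE_LONG, 1L, nc),
      .tiff_entry(257L, TIFF_TYPE_LONG, 1L, nr),
      .tiff_entry(258L, TIFF_TYPE_SHORT, 1L, bits),
      .tiff_entry(259L, TIFF_TYPE_SHORT, 1L, 1L),   # no compression
      .tiff_entry(262L, TIFF_TYPE_SHORT, 1L, 1L),   # black is zero
      .tiff_entry(273L, TIFF_TYPE_LONG, 1L, strip_off),
      .tiff_entry(277L, TIFF_TYPE_SHORT, 1L, 1L),
      .tiff_entry(278L, TIFF_TYPE_LONG, 1L, nr),    # one strip per page
      .tiff_entry(279L, TIFF_TYPE_LONG, 1L, strip_len),
      .tiff_entry(339L, TIFF_TYPE_SHORT, 1L, if (bits == 32L) 3L else 1L)
    )
    writeBin(.le_int(10L, 2L), con)
    writeBin(entries, con)
    writeBin(.le_int(next_ifd, 4L), con)
  }
  for (t in seq_len(nt)) {
    page <- t(frames[, , t])  # TIFF is row-major
    if (bits == 32L) {
      writeBin(as.numeric(page), con, size = 4L, endian = "little")
    } else {
      v <- pmin(pmax(round(as.numeric(page)), 0), 2^bits - 1)
      writeBin(as.integer(v), con, size = bytes_px, endian = "little")
    }
  }
  invisible(path)
}

.read_bytes <- function(bytes, off, what, n, size, endian, signed = TRUE) {
  # readBin only honours `signed` for 1- and 2-byte integers
  if (size > 2L) signed <- TRUE
  readBin(bytes[(off + 1L):(off + n * size)], what = what, n = n,
          size = size, endian = endian, signed = signed)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed single-sample images with 8/16-bit unsigned or
#' 32-bit float pixels, little- or big-endian, one or more strips per page.
#'
#' @param path TIFF file path.
#' @return 3D numeric array `[rows, cols, frames]`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- .read_bytes(bytes, 2L, "integer", 1L, 2L, endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- .read_bytes(bytes, 4L, "integer", 1L, 4L, endian)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- .read_bytes(bytes, ifd_off, "integer", 1L, 2L, endian, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- .read_bytes(bytes, e, "integer", 1L, 2L, endian, signed = FALSE)
      type <- .read_bytes(bytes, e + 2L, "integer", 1L, 2L, endian, signed = FALSE)
      count <- .read_bytes(bytes, e + 4L, "integer", 1L, 4L, endian)
      size <- switch(as.character(type), `3` = 2L, `4` = 4L, `1` = 1L, NA_integer_)
      if (is.na(size)) next  # skip types we do not use
      vals <- if (count * size <= 4L) {
        .read_bytes(bytes, e + 8L, "integer", count, size, endian, signed = FALSE)
      } else {
        voff <- .read_bytes(bytes, e + 8L, "integer", 1L, 4L, endian)
        .read_bytes(bytes, voff, "integer", count, size, endian, signed = FALSE)
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", tag)
        default
      } else v
    }
    nc <- need(256L); nr <- need(257L)
    bits <- need(258L, 8L)
    if (need(259L, 1L) != 1L) stop("compressed TIFF not supported")
    fmt <- need(339L, 1L)
    offs <- need(273L); counts <- need(279L, nr * nc * bits / 8L)
    raw_px <- do.call(c, lapply(seq_along(offs), function(i) {
      bytes[(offs[i] + 1L):(offs[i] + counts[i])]
    }))
    n_px <- nr * nc
    px <- if (bits == 32L && fmt == 3L) {
      readBin(raw_px, "numeric", n = n_px, size = 4L, endian = endian)
    } else if (bits %in% c(8L, 16L) && fmt == 1L) {
      as.numeric(readBin(raw_px, "integer", n = n_px, size = bits / 8L,
                         endian = endian, signed = FALSE))
    } else {
      stop("unsupported TIFF pixel type: ", bits, "-bit, sample format ", fmt)
    }
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = nc, ncol = nr))
    ifd_off <- .read_bytes(bytes, ifd_off + 2L + n_entries * 12L, "integer", 1L, 4L, endian)
  }
  if (!length(pages)) stop("TIFF contains no images")
  dims <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), dims), logical(1))))
    stop("inconsistent frame shapes in TIFF stack")
  array(unlist(pages), c(dims, length(pages)))
}
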