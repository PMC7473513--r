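# Minimal baseline TIFF codec: little-endian, uncompressed, single-sample
# 16-bit unsigned grayscale, one strip per page. No R TIFF package is
# available in the target environment, so the subset of the format this
# package needs is implemented here and round-trip tested.

#' Write a multi-page 16-bit grayscale TIFF
#'
#' Values are rounded and clamped to `[0, 65535]`. One page per frame.
#'
#' @param x 3-D numeric array `(height, width, frames)` or a 2-D matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  h <- dim(x)[1]; w <- dim(x)[2]; nf <- dim(x)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con)
  w16(42L)
  n_tags <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: header(8) then per page [pixel data][IFD]
  data_bytes <- 2L * h * w
  page_off <- function(k) 8L + (k - 1L) * (data_bytes + ifd_size)
  w32(page_off(1L) + data_bytes)  # offset of first IFD

  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count)
    if (type == 3L && count == 1L) { w16(value); w16(0L) } else w32(value)
  }
  for (k in seq_len(nf)) {
    pix <- round(pmin(pmax(as.vector(t(x[, , k])), 0), 65535))
    pix <- as.integer(pix)
    pix[pix > 32767L] <- pix[pix > 32767L] - 65536L  # two's complement
    writeBin(pix, con, size = 2, endian = "little")
    w16(n_tags)
    tag(256L, 3L, 1L, w)                    # ImageWidth
    tag(257L, 3L, 1L, h)                    # ImageLength
    tag(258L, 3L, 1L, 16L)                  # BitsPerSample
    tag(259L, 3L, 1L, 1L)                   # Compression = none
    tag(262L, 3L, 1L, 1L)                   # Photometric = BlackIsZero
    tag(273L, 4L, 1L, page_off(k))          # StripOffsets
    tag(278L, 3L, 1L, h)                    # RowsPerStrip
    tag(279L, 4L, 1L, data_bytes)           # StripByteCounts
    w32(if (k < nf) page_off(k + 1L) + data_bytes else 0L)  # next IFD
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff_stack()]
#'
#' Supports the baseline subset the writer emits (little-endian,
#' uncompressed, 8- or 16-bit grayscale, any strip layout).
#'
#' @param path file path.
#' @return 3-D numeric array `(height, width, frames)`.
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) {
    as.integer(raw_all[off + 1L]) + 256L * as.integer(raw_all[off + 2L])
  }
  u32 <- function(off) {
    sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(raw_all[1:2]) != "II" || u16(2L) != 42L) {
    stop_invalid("not a little-endian TIFF: ", path)
  }
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd + 2L + (i - 1L) * 12L
      id <- u16(base); type <- u16(base + 2L)
      val <- if (type == 3L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(id)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]] %||% 16L
    if ((tags[["259"]] %||% 1L) != 1L) stop_invalid("compressed TIFF unsupported")
    off <- tags[["273"]]
    npx <- h * w
    if (bits == 16L) {
      lo <- as.integer(raw_all[off + seq(1L, 2L * npx, by = 2L)])
      hi <- as.integer(raw_all[off + seq(2L, 2L * npx, by = 2L)])
      v <- lo + 256L * hi
    } else {
      v <- as.integer(raw_all[off + seq_len(npx)])
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  out <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]]
  out
}
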