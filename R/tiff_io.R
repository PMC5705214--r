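# Minimal multi-page TIFF IO (uncompressed grayscale, little-endian).
# No TIFF-capable R package is available in this stack, so the small subset
# of baseline TIFF needed for camera time-stacks is implemented here:
# 8/16-bit, photometric BlackIsZero, compression "none", one or more strips.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L
TAG_COMPRESSION <- 259L; TAG_PHOTOMETRIC <- 262L; TAG_STRIP_OFFSETS <- 273L
TAG_SAMPLES <- 277L; TAG_ROWS_PER_STRIP <- 278L; TAG_STRIP_BYTES <- 279L

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Writes one uncompressed grayscale page per frame, little-endian, intensity
#' rounded and clipped to `[0, 65535]`.
#'
#' @param movie a [movie_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$frames)
  nt <- d[1L]; Y <- d[2L]; X <- d[3L]
  strip_bytes <- Y * X * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2L, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  ifd0 <- 8L + nt * strip_bytes
  writeBin(ifd0, con, size = 4L, endian = "little")
  for (k in seq_len(nt)) {
    v <- as.integer(round(pmin(pmax(t(movie$frames[k, , , drop = TRUE]), 0),
                               65535)))
    v[v > 32767L] <- v[v > 32767L] - 65536L  # unsigned 16-bit on disk
    writeBin(v, con, size = 2L, endian = "little")
  }
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  ifd_size <- 2L + 9L * 12L + 4L
  for (k in seq_len(nt)) {
    w2(9L)
    entry(TAG_WIDTH, 4L, 1L, X)
    entry(TAG_LENGTH, 4L, 1L, Y)
    entry(TAG_BITS, 3L, 1L, 16L)
    entry(TAG_COMPRESSION, 3L, 1L, 1L)
    entry(TAG_PHOTOMETRIC, 3L, 1L, 1L)
    entry(TAG_STRIP_OFFSETS, 4L, 1L, 8L + (k - 1L) * strip_bytes)
    entry(TAG_SAMPLES, 3L, 1L, 1L)
    entry(TAG_ROWS_PER_STRIP, 4L, 1L, Y)
    entry(TAG_STRIP_BYTES, 4L, 1L, strip_bytes)
    w4(if (k < nt) ifd0 + k * ifd_size else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF into a movie stack
#'
#' Supports uncompressed 8- or 16-bit grayscale pages (the format written by
#' [write_movie_tiff()] and by typical scientific camera software with
#' compression disabled). All pages must share one size.
#'
#' @param path TIFF file path.
#' @param frame_interval seconds per frame to stamp onto the result.
#' @return a [movie_stack()].
#' @export
read_movie_tiff <- function(path, frame_interval = 0.2) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file: ", path)
  rd <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw_all[(off + 1L):(off + n * size)], "integer", n = n,
            size = size, signed = signed, endian = endian)
  }
  if (rd(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  type_bytes <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  pages <- list()
  ifd <- rd(4L, 4L)
  while (ifd != 0L) {
    n_ent <- rd(ifd, 2L)
    tags <- list()
    for (e in seq_len(n_ent)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- rd(off, 2L, signed = FALSE)
      typ <- rd(off + 2L, 2L)
      cnt <- rd(off + 4L, 4L)
      tb <- type_bytes[as.character(typ)]
      if (is.na(tb)) { tags[[as.character(tag)]] <- NULL; next }
      voff <- if (tb * cnt <= 4L) off + 8L else rd(off + 8L, 4L)
      tags[[as.character(tag)]] <-
        rd(voff, tb, n = cnt, signed = tb == 4L)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!identical(g(TAG_COMPRESSION, 1L)[1L], 1L)) {
      stop("only uncompressed TIFF is supported")
    }
    X <- g(TAG_WIDTH)[1L]; Y <- g(TAG_LENGTH)[1L]
    bits <- g(TAG_BITS, 16L)[1L]
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale is supported")
    offs <- g(TAG_STRIP_OFFSETS); byts <- g(TAG_STRIP_BYTES)
    px <- integer(0)
    for (s in seq_along(offs)) {
      nv <- byts[s] %/% (bits %/% 8L)
      v <- rd(offs[s], bits %/% 8L, n = nv, signed = FALSE)
      px <- c(px, v)
    }
    if (length(px) != Y * X) stop("corrupt TIFF strip data")
    pages[[length(pages) + 1L]] <- matrix(px, nrow = Y, byrow = TRUE)
    ifd <- rd(ifd + 2L + n_ent * 12L, 4L)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages")
  d1 <- dim(pages[[1L]])
  frames <- array(0, dim = c(length(pages), d1[1L], d1[2L]))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), d1)) stop("TIFF pages differ in size")
    frames[k, , ] <- pages[[k]]
  }
  movie_stack(frames, frame_interval = frame_interval, bit_depth = 16L)
}
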