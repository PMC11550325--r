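# Minimal PNG codec (8-bit greyscale and 8-bit RGB, no interlace).
# The sandbox R has no PNG package, but base memCompress()/memDecompress()
# expose the zlib stream PNG's IDAT requires, and the CRC-32 lives in
# src/geometry.cpp; the chunk plumbing below is all that is left.

PNG_SIG <- as.raw(c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))

u32_raw <- function(n) {
  as.raw(c(n %/% 16777216, (n %/% 65536) %% 256, (n %/% 256) %% 256, n %% 256))
}

raw_u32 <- function(r) {
  sum(as.integer(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data)), body, u32_raw(crc32_cpp(body)))
}

# pix: integer matrix (grey, values 0..255) or height x width x 3 array (RGB)
png_encode <- function(pix) {
  if (is.matrix(pix)) {
    h <- nrow(pix); w <- ncol(pix); colour_type <- 0L
    rows <- t(pix)  # column of t() = one image row
    raw_rows <- as.raw(as.vector(rows))
    dim(raw_rows) <- c(w, h)
  } else {
    h <- dim(pix)[1L]; w <- dim(pix)[2L]; colour_type <- 2L
    # interleave R,G,B per pixel, rows consecutive
    rr <- aperm(pix, c(3L, 2L, 1L))  # channel, col, row
    raw_rows <- as.raw(as.vector(rr))
    dim(raw_rows) <- c(3L * w, h)
  }
  filtered <- rbind(matrix(as.raw(0L), 1L, h), raw_rows)  # filter byte 0 per row
  ihdr <- c(u32_raw(w), u32_raw(h), as.raw(c(8L, colour_type, 0L, 0L, 0L)))
  c(PNG_SIG,
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(as.vector(filtered), type = "gzip")),
    png_chunk("IEND"))
}

png_write_gray <- function(pix, path) {
  writeBin(png_encode(pix), path)
  invisible(path)
}

png_write_rgb <- function(pix, path) {
  writeBin(png_encode(pix), path)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

# Reads an 8-bit greyscale PNG into an integer matrix; handles filters 0-4.
png_read_gray <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIG))
    stop("format error: not a PNG file: ", path)
  pos <- 9L
  w <- h <- NULL
  idat <- list()
  while (pos + 7L <= length(bytes)) {
    len <- raw_u32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0L) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- raw_u32(data[1:4]); h <- raw_u32(data[5:8])
      bit_depth <- as.integer(data[9L]); colour_type <- as.integer(data[10L])
      if (bit_depth != 8L || colour_type != 0L)
        stop("format error: expected an 8-bit single-channel (greyscale) PNG: ",
             path)
      if (as.integer(data[13L]) != 0L)
        stop("format error: interlaced PNG not supported: ", path)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(w) || !length(idat)) stop("format error: truncated PNG: ", path)
  flt <- memDecompress(do.call(c, idat), type = "gzip")
  stride <- w + 1L
  if (length(flt) != stride * h) stop("format error: bad PNG data length: ", path)
  out <- matrix(0L, nrow = h, ncol = w)
  prev <- integer(w)
  for (r in seq_len(h)) {
    row <- as.integer(flt[((r - 1L) * stride + 2L):((r) * stride)])
    ft <- as.integer(flt[(r - 1L) * stride + 1L])
    cur <- switch(as.character(ft),
      "0" = row,
      "1" = Reduce(function(a, b) (a + b) %% 256L, row, accumulate = TRUE),
      "2" = (row + prev) %% 256L,
      "3" = {
        cur <- integer(w)
        left <- 0L
        for (i in seq_len(w)) {
          cur[i] <- (row[i] + (left + prev[i]) %/% 2L) %% 256L
          left <- cur[i]
        }
        cur
      },
      "4" = {
        cur <- integer(w)
        left <- 0L; ul <- 0L
        for (i in seq_len(w)) {
          cur[i] <- (row[i] + paeth(left, prev[i], ul)) %% 256L
          left <- cur[i]; ul <- prev[i]
        }
        cur
      },
      stop("format error: unknown PNG filter type ", ft))
    out[r, ] <- cur
    prev <- cur
  }
  out
}

#' Write a binary mask as a PNG file
#'
#' Single-channel 8-bit PNG; background pixels are written as 0 and labelled
#' pixels as 255. [read_mask()] on the result reproduces the mask exactly.
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png_write_gray(matrix(ifelse(mask, 255L, 0L), nrow(mask), ncol(mask)), path)
}

#' Read a binary mask from a PNG file
#'
#' The file must be a single-channel 8-bit PNG containing only the values 0
#' (background) and 255 (label); anything else is a format error.
#'
#' @param path Path to the PNG.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  pix <- png_read_gray(path)
  bad <- !(pix == 0L | pix == 255L)
  if (any(bad))
    stop(sprintf("format error: non-binary PNG (found value %d) in %s",
                 pix[which(bad)[1L]], path))
  binary_mask(pix == 255L)
}
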