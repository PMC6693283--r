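# Minimal GIF89a writer and block-walking reader. Frames are quantized to a
# fixed 5x5x5 RGB cube (125 colours padded to a 128-entry global table) and
# encoded with byte-aligned LZW literal codes: with a 7-bit minimum code
# size every pixel is one 8-bit code, and a clear code is emitted before the
# dictionary would force a 9-bit width. Simple, portable, and decodable by
# any compliant reader.

GIF_LEVELS <- 5L  # per-channel quantization levels

uint16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

gif_palette <- function() {
  lv <- as.integer(round(seq(0, 255, length.out = GIF_LEVELS)))
  pal <- expand.grid(b = lv, g = lv, r = lv)[, c("r", "g", "b")]
  pal <- as.matrix(pal)
  rbind(pal, matrix(0L, nrow = 128 - nrow(pal), ncol = 3))
}

# rgb array (H x W x 3, in [0,1]) -> vector of palette indices, row-major
quantize_frame <- function(img) {
  q <- function(ch) pmin(GIF_LEVELS - 1L,
                         as.integer(floor(ch * GIF_LEVELS)))
  r <- q(img[, , 1]); g <- q(img[, , 2]); b <- q(img[, , 3])
  idx <- r * GIF_LEVELS^2 + g * GIF_LEVELS + b        # matches gif_palette order
  as.integer(t(idx))                                   # row-major scanlines
}

# LZW image data with byte-aligned codes: minimum code size 7, clear = 128,
# EOI = 129; at most 125 literal codes between clear codes so the code
# width never grows past 8 bits.
encode_pixels <- function(idx) {
  clear <- as.raw(128L); eoi <- as.raw(129L)
  n <- length(idx)
  chunks <- split(idx, ceiling(seq_len(n) / 125))
  body <- unlist(lapply(chunks, function(ch) c(clear, as.raw(ch))),
                 use.names = FALSE)
  stream <- c(body, eoi)
  # wrap in <=255-byte sub-blocks
  blocks <- split(stream, ceiling(seq_along(stream) / 255))
  out <- unlist(lapply(blocks, function(b) c(as.raw(length(b)), b)),
                use.names = FALSE)
  c(as.raw(7L), out, as.raw(0L))
}

#' Write an animated GIF
#'
#' @param frames List of RGB arrays (height x width x 3, values in [0, 1],
#'   as returned by [png::readPNG()]); all frames must share dimensions.
#' @param path Output path.
#' @param delay_cs Per-frame delay in hundredths of a second (default 100 =
#'   1 s).
#' @param loop Loop forever (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_gif <- function(frames, path, delay_cs = 100, loop = TRUE) {
  stopifnot(length(frames) >= 1)
  dims <- dim(frames[[1]])
  h <- dims[1]; w <- dims[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(uint16le(w), uint16le(h),
             as.raw(0xF6),            # global table, 128 entries, 8-bit res
             as.raw(0), as.raw(0)), con)
  writeBin(as.raw(t(gif_palette())), con)
  if (loop) {
    writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
               as.raw(c(0x03, 0x01)), uint16le(0L), as.raw(0)), con)
  }
  for (fr in frames) {
    stopifnot(identical(dim(fr)[1:2], dims[1:2]))
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x04)), uint16le(delay_cs),
               as.raw(0), as.raw(0)), con)
    writeBin(c(as.raw(0x2C), uint16le(0L), uint16le(0L),
               uint16le(w), uint16le(h), as.raw(0)), con)
    writeBin(encode_pixels(quantize_frame(fr[, , 1:3, drop = FALSE])), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

#' Count the frames of a GIF file
#'
#' Walks the GIF block structure (skipping colour tables, extensions and
#' image data) and counts image descriptors.
#'
#' @param path Path to a GIF file.
#' @return Integer frame count.
#' @export
gif_frame_count <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(bytes[1:3]) == "GIF")
  p <- 7L                                  # after 6-byte header
  packed <- as.integer(bytes[p + 4])
  p <- p + 7L                              # logical screen descriptor
  if (bitwAnd(packed, 0x80) > 0) {
    p <- p + 3L * 2L^(bitwAnd(packed, 0x07) + 1L)
  }
  skip_subblocks <- function(p) {
    repeat {
      len <- as.integer(bytes[p]); p <- p + 1L
      if (len == 0) return(p)
      p <- p + len
    }
  }
  count <- 0L
  repeat {
    marker <- as.integer(bytes[p]); p <- p + 1L
    if (marker == 0x3B || p > length(bytes)) break
    if (marker == 0x21) {                  # extension: label + sub-blocks
      p <- skip_subblocks(p + 1L)
    } else if (marker == 0x2C) {           # image descriptor
      count <- count + 1L
      ipacked <- as.integer(bytes[p + 8L])
      p <- p + 9L
      if (bitwAnd(ipacked, 0x80) > 0) {
        p <- p + 3L * 2L^(bitwAnd(ipacked, 0x07) + 1L)
      }
      p <- skip_subblocks(p + 1L)          # skip LZW min code size + data
    } else {
      stop("malformed GIF block 0x", sprintf("%02X", marker), call. = FALSE)
    }
  }
  count
}
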