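# Minimal deterministic 8-bit grayscale PNG writer.
#
# No PNG package exists in the target environment, so the format is emitted
# directly: IHDR/IDAT/IEND chunks, zlib stream with *stored* (uncompressed)
# deflate blocks, CRC32 and Adler32 computed here. Stored blocks keep the
# writer trivially byte-deterministic at the cost of file size (~50 KB for a
# 224x224 map), which is fine for runtime artifacts.

# 32-bit xor on doubles in [0, 2^32)
x32_xor <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    poly <- 3988292384  # 0xEDB88320
    tab <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) x32_xor(c %/% 2, poly) else c %/% 2
      }
      tab[n + 1] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  b <- as.integer(bytes)
  crc <- 4294967295
  for (i in seq_along(b)) {
    crc <- x32_xor(tab[bitwXor(as.integer(crc %% 256), b[i]) + 1L],
                   crc %/% 256)
  }
  4294967295 - crc  # final xor with 0xFFFFFFFF
}

adler32 <- function(bytes) {
  b <- as.integer(bytes)
  n <- length(b)
  s1 <- (1 + sum(b)) %% 65521
  s2 <- if (n) (n + sum((n - seq_len(n) + 1) * b)) %% 65521 else 0
  s2 * 65536 + s1
}

u32_be <- function(v) {
  as.raw(c(v %/% 16777216 %% 256, v %/% 65536 %% 256, v %/% 256 %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(as.raw(utf8ToInt(type)), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# deflate "stored" blocks wrapped in a zlib stream
zlib_stored <- function(data) {
  n <- length(data)
  out <- list(as.raw(c(0x78, 0x01)))
  pos <- 0L
  repeat {
    len <- min(65535L, n - pos)
    last <- pos + len >= n
    hdr <- as.raw(c(if (last) 0x01 else 0x00,
                    len %% 256, len %/% 256,
                    bitwXor(len, 65535L) %% 256, bitwXor(len, 65535L) %/% 256))
    out[[length(out) + 1L]] <- c(hdr, if (len) data[(pos + 1L):(pos + len)] else raw(0))
    pos <- pos + len
    if (last) break
  }
  out[[length(out) + 1L]] <- u32_be(adler32(data))
  do.call(c, out)
}

# pix: integer matrix (rows x cols) of 0..255, row 1 = TOP scanline
write_png_gray <- function(pix, path) {
  rows <- nrow(pix); cols <- ncol(pix)
  stopifnot(all(pix >= 0 & pix <= 255))
  scan <- as.raw(rbind(0L, t(pix)))  # filter byte 0 before each row
  ihdr <- c(u32_be(cols), u32_be(rows),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))  # 8-bit, grayscale
  bytes <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", zlib_stored(scan)),
    png_chunk("IEND", raw(0))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

#' Render a density map to an 8-bit grayscale PNG
#'
#' The map is normalized (linearly, unless already normalized) and written
#' as a `rows x cols` grayscale PNG with `v` increasing upward. The output
#' is byte-deterministic for identical input.
#'
#' @param dm A `psar_density`.
#' @param path Output file path.
#' @param colormap `"gray"` (high density = white) or `"inverted"`.
#' @return The path, invisibly.
#' @export
render_image <- function(dm, path, colormap = c("gray", "inverted")) {
  colormap <- match.arg(colormap)
  stopifnot(inherits(dm, "psar_density"))
  if (!dm$normalized) dm <- normalize_density(dm, "linear")
  pix <- round(255 * dm$grid)
  if (colormap == "inverted") pix <- 255 - pix
  pix <- pix[rev(seq_len(nrow(pix))), , drop = FALSE]  # v increases upward
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Directory does not exist: %s", dir), class = "psar_error_io")
  }
  write_png_gray(pix, path)
  invisible(path)
}
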