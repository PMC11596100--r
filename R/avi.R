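# Uncompressed AVI (RIFF) reader/writer for 8-bit grayscale cine loops.
#
# Frames are stored as bottom-up device-independent bitmaps (BI_RGB): 8-bit
# palettized with a grayscale palette on write; 8-bit palettized or 24-bit
# RGB accepted on read. Compressed FourCC streams are rejected.

fourcc <- function(s) charToRaw(s)

write_avi_cine <- function(loop, path) {
  frames <- loop$frames
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  n <- length(frames)
  fps <- loop$frame_rate %||% 30
  stride <- ceiling(w / 4) * 4
  frame_bytes <- stride * h

  # bottom-up rows, zero-padded to a 4-byte stride
  dib <- function(f) {
    m <- matrix(as.raw(0L), nrow = stride, ncol = h)
    m[seq_len(w), ] <- as.raw(t(f[h:1, , drop = FALSE]))
    as.vector(m)
  }

  avih <- c(uint32le(round(1e6 / fps)), uint32le(frame_bytes * ceiling(fps)),
            uint32le(0L), uint32le(0x10L),  # AVIF_HASINDEX
            uint32le(n), uint32le(0L), uint32le(1L),
            uint32le(frame_bytes), uint32le(w), uint32le(h),
            uint32le(rep(0L, 4L)))
  # dwScale/dwRate as a rational frame rate (per-1000 resolution)
  strh <- c(fourcc("vids"), fourcc("DIB "), uint32le(0L),
            uint32le(0L), uint32le(0L),
            uint32le(1000L), uint32le(round(fps * 1000)),
            uint32le(0L), uint32le(n), uint32le(frame_bytes),
            uint32le(0L), uint32le(0L),
            uint16le(c(0L, 0L)), uint16le(c(w, h)))
  palette <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0L, 256L))))
  strf <- c(uint32le(40L), uint32le(w), uint32le(h), uint16le(1L),
            uint16le(8L), uint32le(0L),  # BI_RGB
            uint32le(frame_bytes), uint32le(0L), uint32le(0L),
            uint32le(256L), uint32le(0L), palette)

  chunk <- function(id, body) c(fourcc(id), uint32le(length(body)), body)
  list_chunk <- function(type, body)
    c(fourcc("LIST"), uint32le(length(body) + 4L), fourcc(type), body)

  strl <- list_chunk("strl", c(chunk("strh", strh), chunk("strf", strf)))
  hdrl <- list_chunk("hdrl", c(chunk("avih", avih), strl))

  movi_frames <- lapply(frames, function(f) chunk("00db", dib(f)))
  movi <- list_chunk("movi", unlist(movi_frames, use.names = FALSE))

  offsets <- 4L + cumsum(c(0L, rep(frame_bytes + 8L, n - 1L)))
  idx1 <- unlist(lapply(seq_len(n), function(i)
    c(fourcc("00db"), uint32le(0x10L), uint32le(offsets[i]),
      uint32le(frame_bytes))), use.names = FALSE)

  body <- c(fourcc("AVI "), hdrl, movi, chunk("idx1", idx1))
  writeBin(c(fourcc("RIFF"), uint32le(length(body)), body), path)
  invisible(path)
}

read_avi_cine <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 24L || rawToChar(r[1:4]) != "RIFF" ||
      rawToChar(r[9:12]) != "AVI ")
    stop("not an AVI file: ", path)

  info <- new.env(parent = emptyenv())
  info$frames <- list()

  walk <- function(pos, end) {
    while (pos + 8L <= end) {
      id <- rawToChar(r[pos:(pos + 3L)])
      len <- r_uint32(r, pos + 4L)
      body_start <- pos + 8L
      if (id == "LIST") {
        walk(body_start + 4L, body_start + len)
      } else if (id == "avih") {
        usec <- r_uint32(r, body_start)
        if (usec > 0) info$fps <- 1e6 / usec
      } else if (id == "strh") {
        if (rawToChar(r[body_start:(body_start + 3L)]) == "vids") {
          scale <- r_uint32(r, body_start + 20L)
          rate <- r_uint32(r, body_start + 24L)
          if (scale > 0 && rate > 0) info$fps <- rate / scale
        }
      } else if (id == "strf" && is.null(info$width)) {
        info$width <- r_uint32(r, body_start + 4L)
        biheight <- r_uint32(r, body_start + 8L)
        info$topdown <- biheight >= 2^31
        info$height <- if (info$topdown) 2^32 - biheight else biheight
        info$bitcount <- r_uint16(r, body_start + 14L)
        compression <- r_uint32(r, body_start + 16L)
        if (compression != 0)
          stop("compressed AVI streams are not supported (FourCC code ",
               compression, "); only uncompressed DIB frames can be read")
        if (r_uint32(r, body_start) >= 40 && info$bitcount == 8L) {
          pal_start <- body_start + 40L
          n_col <- r_uint32(r, body_start + 32L)
          if (n_col == 0) n_col <- 256
          pal <- r[pal_start:(pal_start + 4L * n_col - 1L)]
          b <- as.integer(pal[seq(1L, length(pal), 4L)])
          g <- as.integer(pal[seq(2L, length(pal), 4L)])
          rd <- as.integer(pal[seq(3L, length(pal), 4L)])
          lum <- round(0.299 * rd + 0.587 * g + 0.114 * b)
          info$palette <- c(lum, rep(0L, 256L - n_col))
        }
      } else if (id %in% c("00db", "00dc") && len > 0) {
        info$frames[[length(info$frames) + 1L]] <-
          r[body_start:(body_start + len - 1L)]
      }
      pos <- body_start + len + (len %% 2L)  # chunks are word-aligned
    }
  }
  walk(13L, length(r))

  if (is.null(info$width)) stop("AVI file has no video stream header: ", path)
  if (length(info$frames) == 0L) stop("AVI file contains no frames: ", path)
  h <- info$height; w <- info$width
  frames <- lapply(info$frames, function(b) {
    if (info$bitcount == 8L) {
      stride <- ceiling(w / 4) * 4
      m <- matrix(as.integer(b[seq_len(stride * h)]), nrow = stride)[seq_len(w), ]
      m <- t(m)
      if (!isTRUE(info$topdown)) m <- m[h:1, , drop = FALSE]
      if (!is.null(info$palette)) m[] <- info$palette[m + 1L]
      m
    } else if (info$bitcount == 24L) {
      stride <- ceiling(3 * w / 4) * 4
      v <- as.integer(b[seq_len(stride * h)])
      dim(v) <- c(stride, h)
      bch <- v[seq(1L, 3L * w, 3L), ]; gch <- v[seq(2L, 3L * w, 3L), ]
      rch <- v[seq(3L, 3L * w, 3L), ]
      m <- t(round(0.299 * rch + 0.587 * gch + 0.114 * bch))
      if (!isTRUE(info$topdown)) m <- m[h:1, , drop = FALSE]
      m
    } else stop("unsupported AVI bit depth: ", info$bitcount)
  })
  cine_loop(frames, frame_rate = info$fps, source_format = "avi")
}
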