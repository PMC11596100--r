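# Minimal multi-frame DICOM reader/writer for 8-bit ultrasound cine loops.
#
# Scope: implicit- and explicit-VR little-endian transfer syntaxes plus RLE
# (PackBits) compression; MONOCHROME1/MONOCHROME2 and interleaved RGB photometric
# interpretations; 8 bits allocated. Vendor-proprietary and JPEG-family
# codecs are out of scope.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_RLE <- "1.2.840.10008.1.2.5"
UID_US_MULTIFRAME <- "1.2.840.10008.5.1.4.1.1.3.1"

# ---- byte helpers ----------------------------------------------------------

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

r_uint16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])

r_uint32 <- function(r, i) {
  as.double(r[i]) + 256 * as.double(r[i + 1L]) +
    65536 * as.double(r[i + 2L]) + 16777216 * as.double(r[i + 3L])
}

# string value with trailing NUL/space padding removed
r_string <- function(r, i, len) {
  if (len == 0L) return("")
  v <- r[i:(i + len - 1L)]
  while (length(v) && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  trimws(rawToChar(v))
}

pad_even <- function(v, pad = as.raw(0L)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

# deterministic pseudo-unique suffix from the pixel bytes
pixel_checksum <- function(bytes) {
  v <- as.double(bytes)
  w <- (seq_along(v) - 1) %% 251 + 1
  format(sum(v * w) %% 999999937, scientific = FALSE)
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  if (is.character(value))
    value <- charToRaw(paste(value, collapse = "\\"))
  if (vr %in% c("UI")) value <- pad_even(value, as.raw(0L))
  else if (vr %in% LONG_VRS) value <- pad_even(value, as.raw(0L))
  else value <- pad_even(value, charToRaw(" "))
  head <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS)
    c(head, as.raw(c(0L, 0L)), uint32le(length(value)), value)
  else
    c(head, uint16le(length(value)), value)
}

dcm_element_implicit <- function(group, element, value, pad = as.raw(0L)) {
  if (is.character(value)) value <- charToRaw(value)
  value <- pad_even(value, pad)
  c(uint16le(group), uint16le(element), uint32le(length(value)), value)
}

# ---- writer ----------------------------------------------------------------

write_dicom_cine <- function(loop, path,
                             transfer_syntax = c("explicit", "implicit",
                                                 "rle"),
                             photometric = c("MONOCHROME2", "MONOCHROME1")) {
  transfer_syntax <- match.arg(transfer_syntax)
  photometric <- match.arg(photometric)
  frames <- loop$frames
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  n <- length(frames)
  # DICOM stores rows top-to-bottom, left-to-right: transpose each matrix
  pix <- as.raw(unlist(lapply(frames, function(f) as.integer(t(f))),
                       use.names = FALSE))
  ts_uid <- switch(transfer_syntax, explicit = UID_EXPLICIT_LE,
                   implicit = UID_IMPLICIT_LE, rle = UID_RLE)
  sop_uid <- paste0("1.2.826.0.1.3680043.9999.1.", h, ".", w, ".", n, ".",
                    pixel_checksum(pix))

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", UID_US_MULTIFRAME),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", ts_uid),
    dcm_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.0.1"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32le(length(meta_body))),
            meta_body)

  el <- function(group, element, vr, value) {
    if (transfer_syntax == "implicit")
      dcm_element_implicit(group, element, value,
                           pad = if (vr %in% c("UI", "OB"))
                             as.raw(0L) else charToRaw(" "))
    else dcm_element(group, element, vr, value)
  }
  ds <- c(
    el(0x0008, 0x0016, "UI", UID_US_MULTIFRAME),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "US"),
    if (!is.null(loop$frame_rate))
      el(0x0018, 0x1063, "DS",
         format(1000 / loop$frame_rate, digits = 10)),
    el(0x0028, 0x0002, "US", uint16le(1L)),
    el(0x0028, 0x0004, "CS", photometric),
    el(0x0028, 0x0008, "IS", as.character(n)),
    el(0x0028, 0x0010, "US", uint16le(h)),
    el(0x0028, 0x0011, "US", uint16le(w)),
    el(0x0028, 0x0100, "US", uint16le(8L)),
    el(0x0028, 0x0101, "US", uint16le(8L)),
    el(0x0028, 0x0102, "US", uint16le(7L)),
    el(0x0028, 0x0103, "US", uint16le(0L)))

  if (transfer_syntax == "rle") {
    frag <- lapply(seq_len(n), function(i) {
      off <- (i - 1L) * h * w
      rle_encode_fragment(pix[(off + 1L):(off + h * w)])
    })
    items <- c(
      c(uint16le(0xFFFE), uint16le(0xE000), uint32le(0L)),  # offset table
      unlist(lapply(frag, function(fr)
        c(uint16le(0xFFFE), uint16le(0xE000), uint32le(length(fr)), fr)),
        use.names = FALSE))
    pixel_el <- c(uint16le(0x7FE0), uint16le(0x0010), charToRaw("OB"),
                  as.raw(c(0L, 0L)), as.raw(rep(255L, 4L)),  # undefined len
                  items,
                  uint16le(0xFFFE), uint16le(0xE0DD), uint32le(0L))
  } else if (transfer_syntax == "implicit") {
    pixel_el <- dcm_element_implicit(0x7FE0, 0x0010, pad_even(pix))
  } else {
    pixel_el <- dcm_element(0x7FE0, 0x0010, "OB", pix)
  }

  out <- c(as.raw(rep(0L, 128L)), charToRaw("DICM"), meta, ds, pixel_el)
  writeBin(out, path)
  invisible(path)
}

# one RLE segment (8-bit single-sample data): 64-byte header + PackBits
rle_encode_fragment <- function(bytes) {
  runs <- rle(as.integer(bytes))
  parts <- vector("list", length(runs$lengths))
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]; val <- as.raw(runs$values[i])
    chunks <- raw(0)
    while (len > 0L) {
      take <- min(len, 128L)
      chunks <- c(chunks,
                  if (take == 1L) c(as.raw(0L), val)
                  else c(as.raw(257L - take), val))
      len <- len - take
    }
    parts[[i]] <- chunks
  }
  seg <- unlist(parts, use.names = FALSE)
  header <- c(uint32le(1L), uint32le(64L), uint32le(rep(0L, 14L)))
  pad_even(c(header, seg))
}

rle_decode_fragment <- function(frag, n_out) {
  nseg <- r_uint32(frag, 1L)
  if (nseg != 1)
    stop("RLE pixel data with ", nseg, " segments per frame is not supported")
  off <- r_uint32(frag, 5L) + 1L
  out <- raw(n_out)
  pos <- 1L
  i <- off
  nfrag <- length(frag)
  while (pos <= n_out && i <= nfrag) {
    ctl <- as.integer(frag[i])
    if (ctl <= 127L) {
      cnt <- ctl + 1L
      out[pos:(pos + cnt - 1L)] <- frag[(i + 1L):(i + cnt)]
      i <- i + cnt + 1L
    } else if (ctl >= 129L) {
      cnt <- 257L - ctl
      out[pos:(pos + cnt - 1L)] <- frag[i + 1L]
      i <- i + 2L
    } else {  # 128: no-op
      i <- i + 1L
      next
    }
    pos <- pos + cnt
  }
  if (pos - 1L < n_out)
    stop("corrupt RLE stream: decoded ", pos - 1L, " of ", n_out, " bytes")
  out
}

# ---- reader ----------------------------------------------------------------

read_dicom_cine <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 140L) stop("not a DICOM file (too short): ", path)
  pos <- if (rawToChar(r[129:132]) == "DICM") 133L else 1L

  ts <- UID_IMPLICIT_LE
  tags <- new.env(parent = emptyenv())
  n_total <- length(r)

  # file meta group (0002,xxxx) is always explicit VR little endian
  while (pos + 7L <= n_total && r_uint16(r, pos) == 2L) {
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- r_uint32(r, pos + 8L); vstart <- pos + 12L
    } else {
      len <- r_uint16(r, pos + 6L); vstart <- pos + 8L
    }
    if (r_uint16(r, pos + 2L) == 0x0010)
      ts <- r_string(r, vstart, len)
    pos <- vstart + len
  }
  explicit <- !identical(ts, UID_IMPLICIT_LE)
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE, UID_RLE))
    stop("unsupported DICOM transfer syntax: ", ts,
         " (supported: uncompressed little-endian and RLE)")

  while (pos + 7L <= n_total) {
    group <- r_uint16(r, pos); element <- r_uint16(r, pos + 2L)
    if (explicit) {
      vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- r_uint32(r, pos + 8L); vstart <- pos + 12L
      } else {
        len <- r_uint16(r, pos + 6L); vstart <- pos + 8L
      }
    } else {
      vr <- "UN"
      len <- r_uint32(r, pos + 4L); vstart <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, element)
    if (len == 4294967295) {  # undefined length
      if (group == 0x7FE0 && element == 0x0010) {
        parsed <- parse_encapsulated(r, vstart)
        tags$fragments <- parsed$fragments
        pos <- parsed$pos
      } else {
        pos <- skip_undefined_sequence(r, vstart)
      }
      next
    }
    if (key %in% c("00280010", "00280011", "00280002", "00280006",
                   "00280100", "00280103")) {
      tags[[key]] <- r_uint16(r, vstart)
    } else if (key %in% c("00280004", "00280008", "00181063", "00082144")) {
      tags[[key]] <- r_string(r, vstart, len)
    } else if (key == "7FE00010") {
      tags$pixeldata <- r[vstart:(vstart + len - 1L)]
    }
    pos <- vstart + len
  }

  rows <- tags[["00280010"]]; cols <- tags[["00280011"]]
  if (is.null(rows) || is.null(cols))
    stop("DICOM file has no Rows/Columns attributes: ", path)
  spp <- tags[["00280002"]] %||% 1L
  nframes <- as.integer(tags[["00280008"]] %||% "1")
  photometric <- tags[["00280004"]] %||% "MONOCHROME2"
  bits <- tags[["00280100"]] %||% 8L
  if (bits != 8L)
    stop("only 8-bit DICOM pixel data is supported (BitsAllocated = ",
         bits, ")")

  npix <- rows * cols * spp
  if (!is.null(tags$fragments)) {
    if (length(tags$fragments) < nframes)
      stop("encapsulated DICOM holds ", length(tags$fragments),
           " fragments for ", nframes, " frames")
    pix <- unlist(lapply(tags$fragments[seq_len(nframes)],
                         rle_decode_fragment, n_out = npix),
                  use.names = FALSE)
  } else {
    if (is.null(tags$pixeldata)) stop("DICOM file has no pixel data: ", path)
    if (length(tags$pixeldata) < npix * nframes)
      stop("DICOM pixel data truncated: expected ", npix * nframes,
           " bytes, found ", length(tags$pixeldata))
    pix <- tags$pixeldata[seq_len(npix * nframes)]
  }
  vals <- as.integer(pix)

  frames <- vector("list", nframes)
  per_frame <- npix
  for (i in seq_len(nframes)) {
    fv <- vals[((i - 1L) * per_frame + 1L):(i * per_frame)]
    if (spp == 3L) {
      planar <- tags[["00280006"]] %||% 0L
      if (planar == 0L) {
        rch <- fv[seq(1L, length(fv), 3L)]
        gch <- fv[seq(2L, length(fv), 3L)]
        bch <- fv[seq(3L, length(fv), 3L)]
      } else {
        k <- rows * cols
        rch <- fv[1:k]; gch <- fv[(k + 1L):(2L * k)]
        bch <- fv[(2L * k + 1L):(3L * k)]
      }
      fv <- round(0.299 * rch + 0.587 * gch + 0.114 * bch)
    }
    m <- matrix(fv, nrow = rows, ncol = cols, byrow = TRUE)
    if (photometric == "MONOCHROME1") m <- 255L - m
    frames[[i]] <- m
  }

  fr <- NULL
  if (!is.null(tags[["00181063"]])) {
    ft <- suppressWarnings(as.numeric(tags[["00181063"]]))
    if (isTRUE(is.finite(ft)) && ft > 0) fr <- 1000 / ft
  } else if (!is.null(tags[["00082144"]])) {
    fps <- suppressWarnings(as.numeric(tags[["00082144"]]))
    if (isTRUE(is.finite(fps)) && fps > 0) fr <- fps
  }
  cine_loop(frames, frame_rate = fr, source_format = "dicom")
}

parse_encapsulated <- function(r, pos) {
  frags <- list()
  first <- TRUE
  repeat {
    group <- r_uint16(r, pos); element <- r_uint16(r, pos + 2L)
    len <- r_uint32(r, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break
    if (group != 0xFFFE || element != 0xE000)
      stop("corrupt encapsulated pixel data")
    if (first) {
      first <- FALSE  # basic offset table, ignored
    } else if (len > 0) {
      frags[[length(frags) + 1L]] <- r[pos:(pos + len - 1L)]
    }
    pos <- pos + len
  }
  list(fragments = frags, pos = pos)
}

skip_undefined_sequence <- function(r, pos) {
  repeat {
    group <- r_uint16(r, pos); element <- r_uint16(r, pos + 2L)
    len <- r_uint32(r, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) return(pos)
    if (group == 0xFFFE && element == 0xE000) {
      pos <- if (len == 4294967295) skip_undefined_item(r, pos)
             else pos + len
    } else stop("corrupt sequence while skipping undefined-length element")
  }
}

skip_undefined_item <- function(r, pos) {
  repeat {
    group <- r_uint16(r, pos); element <- r_uint16(r, pos + 2L)
    len <- r_uint32(r, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE00D) return(pos)
    pos <- pos + if (len == 4294967295) stop("nested undefined lengths") else len
  }
}
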