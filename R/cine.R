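#' Echocardiography cine loop container
#'
#' A cine loop is an ordered sequence of 8-bit grayscale frames sharing one
#' set of dimensions, with an optional frame rate.
#'
#' @param frames List of numeric matrices with integer values in \[0, 255\],
#'   all of identical dimensions. Color frames (H x W x 3 arrays) are
#'   reduced to Rec. 601 luminance and rounded.
#' @param frame_rate Frames per second (positive), or `NULL` if unknown.
#' @param source_format Optional tag recording where the loop came from
#'   (`"dicom"`, `"avi"`, `"png-sequence"`, ...).
#' @return An object of class `cine_loop`.
#' @examples
#' cine_loop(list(matrix(0, 4, 4), matrix(255, 4, 4)), frame_rate = 30)
#' @export
cine_loop <- function(frames, frame_rate = NULL, source_format = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("a cine loop needs at least one frame")
  frames <- lapply(frames, function(f) {
    f <- to_luminance(f)
    if (!is.matrix(f) || !is.numeric(f))
      stop("each frame must be a numeric matrix")
    f <- round(f)
    if (min(f) < 0 || max(f) > 255)
      stop("frame values must lie in [0, 255]")
    storage.mode(f) <- "integer"
    f
  })
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d1))
      stop(sprintf("frame %d is %d x %d but frame 1 is %d x %d",
                   i, nrow(frames[[i]]), ncol(frames[[i]]), d1[1L], d1[2L]))
  if (!is.null(frame_rate)) {
    if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
        is.na(frame_rate) || frame_rate <= 0)
      stop("'frame_rate' must be a single positive number")
    frame_rate <- as.numeric(frame_rate)
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 source_format = source_format),
            class = "cine_loop")
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Cine loop: %d frame(s) of %d x %d pixels%s%s\n",
              length(x$frames), d[1L], d[2L],
              if (is.null(x$frame_rate)) ""
              else sprintf(" at %g fps", x$frame_rate),
              if (is.null(x$source_format)) ""
              else sprintf(" [%s]", x$source_format)))
  invisible(x)
}

#' @export
length.cine_loop <- function(x) length(x$frames)

#' Dimensions of a cine loop
#'
#' @param x A [cine_loop()].
#' @return `c(height, width, n_frames)`.
#' @export
dim.cine_loop <- function(x) c(dim(x$frames[[1L]]), length(x$frames))

detect_cine_format <- function(path) {
  if (dir.exists(path)) return("png-sequence")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         dcm = , dicom = "dicom",
         avi = "avi",
         png = "png-sequence",
         mp4 = , mov = , mkv = stop(
           "compressed video containers (", ext, ") are not supported; ",
           "use multi-frame DICOM, uncompressed AVI or a PNG sequence"),
         stop("cannot infer cine format from path: ", path))
}

#' Read an echocardiography cine loop
#'
#' Supported containers:
#' * multi-frame DICOM (`.dcm`): uncompressed implicit/explicit-VR
#'   little-endian and RLE-compressed pixel data; `MONOCHROME1` is inverted
#'   to the `MONOCHROME2` convention and RGB data is reduced to luminance;
#'   the frame rate is recovered from Frame Time or Recommended Display
#'   Frame Rate when present;
#' * AVI (`.avi`): uncompressed 8-bit palettized or 24-bit RGB DIB frames;
#' * PNG sequence: a directory of numbered `.png` files (sorted by name),
#'   or a single `.png` file as a 1-frame loop.
#'
#' @param path File (DICOM, AVI, single PNG) or directory (PNG sequence).
#' @param format Override the format inferred from the path; one of
#'   `"dicom"`, `"avi"`, `"png-sequence"`.
#' @return A [cine_loop()].
#' @export
read_cine <- function(path, format = NULL) {
  if (!file.exists(path)) stop("input not found: ", path)
  format <- format %||% detect_cine_format(path)
  switch(format,
         dicom = read_dicom_cine(path),
         avi = read_avi_cine(path),
         `png-sequence` = read_png_sequence(path),
         stop("unsupported format: ", format))
}

#' Write an echocardiography cine loop
#'
#' DICOM and PNG-sequence output round-trip bit-exactly. AVI output uses
#' uncompressed 8-bit DIB frames, which also round-trip exactly (at the cost
#' of file size). Writing is deterministic: the same loop always produces
#' byte-identical files.
#'
#' @param loop A [cine_loop()].
#' @param path Output file (DICOM, AVI) or directory (PNG sequence).
#' @param format One of `"dicom"`, `"avi"`, `"png-sequence"`; inferred from
#'   `path` when omitted.
#' @param ... Passed to the format-specific writer (e.g. `transfer_syntax`
#'   for DICOM: `"explicit"`, `"implicit"` or `"rle"`).
#' @return `path`, invisibly.
#' @export
write_cine <- function(loop, path, format = NULL, ...) {
  if (!inherits(loop, "cine_loop")) stop("'loop' must be a cine_loop")
  format <- format %||% detect_cine_format_out(path)
  switch(format,
         dicom = write_dicom_cine(loop, path, ...),
         avi = write_avi_cine(loop, path),
         `png-sequence` = write_png_sequence(loop, path),
         stop("unsupported format: ", format))
  invisible(path)
}

detect_cine_format_out <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "") "png-sequence" else detect_cine_format(
    if (dir.exists(path)) path else paste0("x.", ext))
}

read_png_sequence <- function(path) {
  files <- if (dir.exists(path)) {
    f <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(f) == 0L) stop("no .png files found in ", path)
    f
  } else path
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    round(to_luminance(img) * 255)
  })
  cine_loop(frames, source_format = "png-sequence")
}

write_png_sequence <- function(loop, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nd <- max(4L, nchar(length(loop$frames)))
  for (i in seq_along(loop$frames)) {
    f <- file.path(path, sprintf("frame_%0*d.png", nd, i))
    png::writePNG(loop$frames[[i]] / 255, f)
  }
  invisible(path)
}
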