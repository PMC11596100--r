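#' Tone-mapping parameters
#'
#' Bundles the contrast parameter of the generalized Reinhard operator with
#' the display-rescale policy.
#'
#' The operator maps normalized intensities through
#' \eqn{I_{out} = I_{in} / (I_{in} + A)}. The classical Reinhard curve is the
#' special case \eqn{A = 1}. For \eqn{A < 1} the low- and mid-tone response
#' steepens (higher contrast); for \eqn{A > 1} it flattens. Because the raw
#' curve maps \eqn{[0, 1]} into \eqn{[0, 1/(1+A)]}, displayed output would
#' darken (at \eqn{A = 1} the attainable maximum is gray level 128 of 255).
#' When `rescale_display` is `TRUE` (the default) the mapped intensities are
#' multiplied by \eqn{1 + A} before quantization so that the attainable
#' maximum uses the full display range; the shape of the tone curve is
#' unchanged by this linear factor.
#'
#' @param A Positive contrast parameter. Default 1.
#' @param rescale_display Logical; linearly restore the full output range
#'   after tone mapping. Default `TRUE`.
#' @return An object of class `tonemap_params`.
#' @examples
#' tonemap_params(A = 0.6)
#' @export
tonemap_params <- function(A = 1, rescale_display = TRUE) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive finite number, got ",
         deparse(substitute(A)), " = ", format(A))
  if (!is.logical(rescale_display) || length(rescale_display) != 1L ||
      is.na(rescale_display))
    stop("'rescale_display' must be TRUE or FALSE")
  structure(list(A = as.numeric(A), rescale_display = rescale_display),
            class = "tonemap_params")
}

#' @export
print.tonemap_params <- function(x, ...) {
  cat(sprintf("Tone-mapping parameters: A = %g (%s contrast than A = 1), %s\n",
              x$A,
              if (x$A < 1) "higher" else if (x$A > 1) "lower" else "reference",
              if (x$rescale_display) "display rescale on" else
                "display rescale off"))
  invisible(x)
}

as_tonemap_params <- function(x) {
  if (inherits(x, "tonemap_params")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(tonemap_params(A = x))
  stop("cannot interpret 'params' as tone-mapping parameters")
}

#' Convert an 8-bit frame to normalized intensities
#'
#' Divides integer gray levels in \[0, 255\] by 255, giving the normalized
#' \[0, 1\] representation in which the tone-mapping operator is defined.
#' Frames carrying color channels (a 3-d array) are first reduced to
#' luminance with Rec. 601 weights (0.299 R + 0.587 G + 0.114 B).
#'
#' @param frame_8bit Numeric matrix (or height x width x 3 array) of integer
#'   gray levels in \[0, 255\].
#' @return Numeric matrix of intensities in \[0, 1\].
#' @examples
#' normalize_intensity(matrix(c(0, 128, 255), 1))
#' @export
normalize_intensity <- function(frame_8bit) {
  if (!is.numeric(frame_8bit))
    stop("'frame_8bit' must be numeric")
  rng <- range(frame_8bit)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf(
      "pixel values must lie in [0, 255]; observed range [%g, %g]",
      rng[1L], rng[2L]))
  if (any(frame_8bit != floor(frame_8bit)))
    stop("pixel values must be integers in [0, 255]")
  frame_8bit <- to_luminance(frame_8bit)  # may be fractional for color input
  if (!is.matrix(frame_8bit))
    stop("'frame_8bit' must be a matrix or an H x W x 3 color array")
  frame_8bit / 255
}

# Rec. 601 luminance for H x W x 3 arrays; matrices pass through.
to_luminance <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3L] == 1L) return(x[, , 1L, drop = TRUE])
    if (dim(x)[3L] < 3L) stop("expected 1 or >=3 channels")
    return(0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L])
  }
  x
}

check_intensity_frame <- function(frame, what = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'", what, "' must be a numeric matrix of normalized intensities")
  rng <- range(frame)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1)
    stop(sprintf(
      "'%s' must hold intensities in [0, 1]; observed range [%g, %g]",
      what, rng[1L], rng[2L]))
  invisible(frame)
}

#' Generalized Reinhard tone-mapping operator
#'
#' Applies \eqn{I_{out} = I_{in} / (I_{in} + A)} elementwise to a normalized
#' intensity frame. The map is strictly increasing in \eqn{I_{in}}, bounded
#' by \eqn{1 / (1 + A)}, and has slope \eqn{1 / A} at the origin, so values
#' of \eqn{A} below 1 amplify the dark-to-mid range relative to the identity
#' while values above 1 attenuate it.
#'
#' @param frame Numeric matrix of intensities in \[0, 1\]
#'   (see [normalize_intensity()]).
#' @param params A [tonemap_params()] object, or a single positive number
#'   taken as `A`.
#' @return Numeric matrix of mapped intensities in \[0, 1/(1+A)\].
#' @examples
#' reinhard_tmo(matrix(c(0, 0.5, 1), 1), tonemap_params(A = 1))
#' @export
reinhard_tmo <- function(frame, params = tonemap_params()) {
  params <- as_tonemap_params(params)
  check_intensity_frame(frame)
  frame / (frame + params$A)
}

#' Convert tone-mapped intensities back to 8-bit gray levels
#'
#' Quantizes a frame produced by [reinhard_tmo()] to integers in \[0, 255\]
#' for display on standard monitors. With `rescale_display` on (the default
#' policy in [tonemap_params()]) the intensities are first multiplied by
#' \eqn{1 + A} so the attainable maximum \eqn{1/(1+A)} maps to 255; with it
#' off, the raw mapped intensities are quantized directly. Quantization
#' rounds half away from zero and clamps to \[0, 255\].
#'
#' @param frame Numeric matrix of tone-mapped intensities.
#' @param params The same [tonemap_params()] used to produce `frame`.
#' @return Numeric matrix of integer gray levels in \[0, 255\].
#' @examples
#' f <- reinhard_tmo(matrix(1), tonemap_params(A = 1))
#' rescale_for_display(f, tonemap_params(A = 1)) # 255
#' @export
rescale_for_display <- function(frame, params = tonemap_params()) {
  params <- as_tonemap_params(params)
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a numeric matrix")
  v <- if (params$rescale_display) frame * (1 + params$A) else frame
  quantize_8bit(v)
}

# round half away from zero, clamp to [0,255]; inputs are non-negative here
quantize_8bit <- function(v) {
  pmin(pmax(floor(255 * v + 0.5), 0), 255)
}
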