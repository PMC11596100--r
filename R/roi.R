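#' Region-of-interest geometry
#'
#' Describes the apical region of interest in resolution-independent
#' normalized coordinates: `x` runs rightward and `y` downward, both in
#' \[0, 1\] with the origin at the top-left corner of the frame. In the
#' standard apical echocardiographic views the left ventricular apex is
#' displayed at the top of the sector, so the default region used by the
#' processing pipeline is the upper portion of the frame (see
#' [default_apical_roi()]).
#'
#' @param shape One of `"rectangle"`, `"ellipse"`, `"polygon"`.
#' @param coords Shape parameters, all normalized to \[0, 1\]:
#'   * rectangle: `c(x0, y0, x1, y1)` (opposite corners);
#'   * ellipse: `c(cx, cy, rx, ry)` (center and semi-axes);
#'   * polygon: a matrix with columns `x`, `y` and at least 3 rows.
#' @param feather_px Non-negative feather width in pixels: mask weights ramp
#'   linearly from 0 at the region boundary to 1 at this depth inside it.
#'   `0` gives a hard binary mask.
#' @return An object of class `roi_geometry`.
#' @examples
#' roi_geometry("rectangle", c(0, 0, 1, 0.4), feather_px = 8)
#' @export
roi_geometry <- function(shape = c("rectangle", "ellipse", "polygon"),
                         coords, feather_px = 8) {
  shape <- match.arg(shape)
  if (!is.numeric(feather_px) || length(feather_px) != 1L ||
      is.na(feather_px) || feather_px < 0)
    stop("'feather_px' must be a single non-negative number")
  if (shape == "polygon") {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2L || nrow(coords) < 3L)
      stop("a polygon needs a 2-column matrix with at least 3 vertices")
  } else {
    coords <- as.numeric(coords)
    if (length(coords) != 4L)
      stop("'", shape, "' needs 4 coordinates")
    if (shape == "ellipse" && any(coords[3:4] < 0))
      stop("ellipse semi-axes must be non-negative")
  }
  if (any(coords < 0) || any(coords > 1))
    stop("normalized coordinates must lie in [0, 1]")
  structure(list(shape = shape, coords = coords,
                 feather_px = as.numeric(feather_px)),
            class = "roi_geometry")
}

#' Default apical region of interest
#'
#' The upper 40% of the frame, where the left ventricular apex sits in a
#' standard apical view, with an 8-pixel feathered boundary so the enhanced
#' region blends into its surroundings without a visible seam.
#'
#' @param feather_px Feather width in pixels (default 8).
#' @return An `roi_geometry` rectangle.
#' @export
default_apical_roi <- function(feather_px = 8) {
  roi_geometry("rectangle", c(0, 0, 1, 0.4), feather_px = feather_px)
}

#' Rasterize a region of interest into a weight mask
#'
#' Pixel centers falling inside the geometry are selected, then the binary
#' mask is feathered: weights ramp linearly with the distance to the region
#' boundary, reaching 1 at `feather_px` pixels inside, and are exactly 0
#' outside. A zero feather yields a hard 0/1 mask. A degenerate (zero-area)
#' geometry yields an all-zero mask with a warning.
#'
#' @param geometry An [roi_geometry()].
#' @param height,width Frame dimensions in pixels.
#' @return Numeric `height` x `width` matrix of weights in \[0, 1\].
#' @examples
#' m <- build_roi_mask(default_apical_roi(), 64, 64)
#' range(m)
#' @export
build_roi_mask <- function(geometry, height, width) {
  if (!inherits(geometry, "roi_geometry"))
    stop("'geometry' must be an roi_geometry object")
  if (height < 1 || width < 1) stop("frame dimensions must be positive")
  # pixel centers in normalized coordinates
  xs <- (seq_len(width) - 0.5) / width
  ys <- (seq_len(height) - 0.5) / height
  X <- matrix(xs, height, width, byrow = TRUE)
  Y <- matrix(ys, height, width)
  co <- geometry$coords
  inside <- switch(geometry$shape,
    rectangle = {
      x0 <- min(co[1L], co[3L]); x1 <- max(co[1L], co[3L])
      y0 <- min(co[2L], co[4L]); y1 <- max(co[2L], co[4L])
      X >= x0 & X <= x1 & Y >= y0 & Y <= y1
    },
    ellipse = {
      if (co[3L] == 0 || co[4L] == 0) matrix(FALSE, height, width)
      else ((X - co[1L]) / co[3L])^2 + ((Y - co[2L]) / co[4L])^2 <= 1
    },
    polygon = {
      matrix(pracma::inpolygon(as.vector(X), as.vector(Y),
                               co[, 1L], co[, 2L], boundary = TRUE),
             height, width)
    })
  if (!any(inside)) {
    warning("degenerate region of interest: mask is empty")
    return(matrix(0, height, width))
  }
  if (geometry$feather_px == 0 || all(inside)) return(inside + 0)
  # distance (in pixels) from each inside pixel to the nearest outside pixel;
  # the frame border does not count as a boundary, so pad with TRUE
  pad <- matrix(TRUE, height + 2L, width + 2L)
  pad[2:(height + 1L), 2:(width + 1L)] <- inside
  d <- EBImage::distmap(pad)[2:(height + 1L), 2:(width + 1L)]
  pmin(d / geometry$feather_px, 1)
}

#' Full processing configuration
#'
#' Combines the tone-mapping parameters, the apical region of interest and
#' the strength of the smoothing applied outside the region.
#'
#' @param tonemap A [tonemap_params()] object.
#' @param roi An [roi_geometry()] object.
#' @param outside_smoothing_sigma Standard deviation, in pixels, of the
#'   Gaussian smoothing applied outside the region of interest; `0` leaves
#'   the outside untouched. Default 1.
#' @return An object of class `processing_config`.
#' @export
processing_config <- function(tonemap = tonemap_params(),
                              roi = default_apical_roi(),
                              outside_smoothing_sigma = 1) {
  tonemap <- as_tonemap_params(tonemap)
  if (!inherits(roi, "roi_geometry"))
    stop("'roi' must be an roi_geometry object")
  if (!is.numeric(outside_smoothing_sigma) ||
      length(outside_smoothing_sigma) != 1L ||
      is.na(outside_smoothing_sigma) || outside_smoothing_sigma < 0)
    stop("'outside_smoothing_sigma' must be a single non-negative number")
  structure(list(tonemap = tonemap, roi = roi,
                 outside_smoothing_sigma = as.numeric(outside_smoothing_sigma)),
            class = "processing_config")
}

#' Read a processing configuration from YAML or JSON
#'
#' The file holds the keys `tonemap.A`, `tonemap.rescale_display`,
#' `roi.shape`, `roi.coords`, `roi.feather_px` and `smoothing.sigma_px`;
#' missing keys fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [processing_config()] object.
#' @export
read_processing_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  tm <- tonemap_params(
    A = cfg$tonemap$A %||% 1,
    rescale_display = cfg$tonemap$rescale_display %||% TRUE)
  roi <- if (is.null(cfg$roi)) default_apical_roi() else {
    co <- cfg$roi$coords
    if (identical(cfg$roi$shape, "polygon")) co <- do.call(rbind, co)
    roi_geometry(shape = cfg$roi$shape %||% "rectangle",
                 coords = co %||% c(0, 0, 1, 0.4),
                 feather_px = cfg$roi$feather_px %||% 8)
  }
  processing_config(tonemap = tm, roi = roi,
                    outside_smoothing_sigma = cfg$smoothing$sigma_px %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gaussian_smooth <- function(frame, sigma) {
  if (sigma == 0) return(frame)
  EBImage::gblur(frame, sigma = sigma, boundary = "replicate")
}

#' Apply the thrombus-detection enhancement to one frame
#'
#' Inside the region of interest the frame is tone-mapped with the
#' generalized Reinhard operator (and, under the default display policy,
#' linearly rescaled by \eqn{1 + A} in normalized units so the tone-mapped
#' range matches the input range); outside it the frame receives a mild
#' Gaussian smoothing. The two versions are blended per pixel by the mask
#' weight: `out = w * T(frame) + (1 - w) * S(frame)`, then clamped to
#' \[0, 1\]. All arithmetic is done on normalized floating-point
#' intensities; quantization to 8 bits happens once, at the end of the
#' pipeline.
#'
#' @param frame Numeric matrix of intensities in \[0, 1\].
#' @param mask Weight matrix from [build_roi_mask()], same dimensions.
#' @param config A [processing_config()].
#' @return Numeric matrix of enhanced intensities in \[0, 1\].
#' @export
apply_lvtdm_frame <- function(frame, mask, config = processing_config()) {
  check_intensity_frame(frame)
  if (!identical(dim(frame), dim(mask)))
    stop(sprintf("frame is %d x %d but mask is %d x %d",
                 nrow(frame), ncol(frame), nrow(mask), ncol(mask)))
  A <- config$tonemap$A
  gain <- if (config$tonemap$rescale_display) 1 + A else 1
  mapped <- gain * frame / (frame + A)
  smoothed <- gaussian_smooth(frame, config$outside_smoothing_sigma)
  out <- mask * mapped + (1 - mask) * smoothed
  pmin(pmax(out, 0), 1)
}

#' Apply the enhancement to a whole cine loop
#'
#' Builds the region-of-interest mask once from the first frame's
#' dimensions and applies [apply_lvtdm_frame()] to every frame with
#' identical parameters; frame count and order are preserved.
#'
#' @param frames List of numeric intensity matrices sharing dimensions.
#' @param config A [processing_config()].
#' @return List of enhanced frames.
#' @export
apply_lvtdm_video <- function(frames, config = processing_config()) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of intensity matrices")
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d1))
      stop(sprintf(
        "frame %d is %d x %d, but frame 1 is %d x %d: dimensions must be constant",
        i, nrow(frames[[i]]), ncol(frames[[i]]), d1[1L], d1[2L]))
  mask <- build_roi_mask(config$roi, d1[1L], d1[2L])
  lapply(frames, apply_lvtdm_frame, mask = mask, config = config)
}
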