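#' Specification of a synthetic B-mode echocardiography phantom
#'
#' Describes a sector-scan grayscale cine loop with fully developed speckle:
#' a dark blood-filled ventricular cavity, a bright myocardial band around
#' it, surrounding tissue, and an optional low-contrast thrombus attached
#' to the cavity apex (displayed at the top of the sector, as in apical
#' echocardiographic views). Geometry is given in normalized coordinates
#' (unit square, origin top-left, y downward).
#'
#' Region intensities are mean reflectivities in \[0, 1\] and must satisfy
#' `cavity_mean < thrombus_mean < myocardium_mean`: blood is nearly
#' anechoic, thrombus is a low-to-mid echogenic mass, myocardium is the
#' brightest of the three. Speckle is multiplicative: the squared magnitude
#' of a unit-variance circular Gaussian field (an exponential variate with
#' mean 1), smoothed by a small point-spread kernel to give it lateral
#' correlation, scaled by `speckle_scale` about its mean. A small periodic
#' inward wall displacement across frames emulates systolic motion.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames (at least 1).
#' @param sector_angle Full opening angle of the imaging sector, degrees.
#' @param cavity_mean,thrombus_mean,myocardium_mean Region mean
#'   reflectivities in \[0, 1\].
#' @param background_mean Mean reflectivity of in-sector tissue outside the
#'   ventricle.
#' @param speckle_scale Non-negative multiplier of the speckle fluctuation;
#'   1 is fully developed speckle, 0 is noiseless.
#' @param thrombus `NULL` for no thrombus, or a list with `center`
#'   (normalized `c(x, y)`) and `axes` (normalized semi-axes `c(rx, ry)`).
#'   The default places a 0.09 x 0.06 half-axis mass at the cavity apex.
#' @param motion_amplitude Peak wall displacement as a fraction of frame
#'   height.
#' @param seed Integer seed making the loop reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256, width = 256, n_frames = 16,
                         sector_angle = 75,
                         cavity_mean = 0.03, thrombus_mean = 0.35,
                         myocardium_mean = 0.75, background_mean = 0.45,
                         speckle_scale = 1,
                         thrombus = list(center = c(0.5, 0.21),
                                         axes = c(0.09, 0.06)),
                         motion_amplitude = 0.02, seed = 1L) {
  if (height < 32 || width < 32) stop("phantom frames must be at least 32 px")
  if (n_frames < 1) stop("'n_frames' must be at least 1")
  if (!(cavity_mean < thrombus_mean && thrombus_mean < myocardium_mean))
    stop("region intensities must satisfy cavity_mean < thrombus_mean < ",
         "myocardium_mean")
  if (any(c(cavity_mean, thrombus_mean, myocardium_mean,
            background_mean) < 0) ||
      any(c(cavity_mean, thrombus_mean, myocardium_mean,
            background_mean) > 1))
    stop("region intensities must lie in [0, 1]")
  if (speckle_scale < 0) stop("'speckle_scale' must be non-negative")
  if (motion_amplitude < 0 || motion_amplitude > 0.2)
    stop("'motion_amplitude' must lie in [0, 0.2]")
  if (!is.null(thrombus)) {
    if (is.null(thrombus$center) || is.null(thrombus$axes))
      stop("'thrombus' needs 'center' and 'axes'")
    if (any(unlist(thrombus) < 0) || any(unlist(thrombus) > 1))
      stop("thrombus geometry must lie within the unit square")
  }
  structure(as.list(environment()), class = "phantom_spec")
}

# 3x3 binomial point-spread kernel
PSF_KERNEL <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)

conv3x3 <- function(m, kernel) {
  h <- nrow(m); w <- ncol(m)
  # replicate-pad by one pixel, then accumulate the 9 shifted copies
  p <- m[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1)
    out <- out + kernel[dy + 2L, dx + 2L] *
      p[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  out
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

inside_ellipse <- function(X, Y, center, axes) {
  if (axes[1L] <= 0 || axes[2L] <= 0) return(X < -1)  # all FALSE
  ((X - center[1L]) / axes[1L])^2 + ((Y - center[2L]) / axes[2L])^2 <= 1
}

#' Generate a synthetic echocardiography cine loop with ground truth
#'
#' Renders the loop described by a [phantom_spec()]: a reflectivity
#' template per frame (sector, cavity, myocardial band, optional apical
#' thrombus, with a sinusoidal inward wall displacement over the cardiac
#' cycle) multiplied by a smoothed exponential speckle field drawn fresh
#' per frame, then quantized to 8 bits. Pixels outside the sector are 0.
#'
#' Ground-truth region masks are returned for the reference (end-diastolic,
#' zero-displacement) geometry, the way a reader would annotate a still
#' frame; pixels near the moving wall therefore mix cavity and myocardium
#' over the cycle, as they do in clinical annotations.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `loop` (a [cine_loop()]) and `masks`, a named list
#'   of logical matrices (`sector`, `cavity`, `myocardium`, `thrombus`).
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64, n_frames = 2))
#' dim(ph$loop)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  xs <- (seq_len(w) - 0.5) / w
  ys <- (seq_len(h) - 0.5) / h
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)

  # sector: wedge from a virtual apex just above the frame, opening downward
  apex <- c(0.5, 0.02)
  ang <- atan2(X - apex[1L], Y - apex[2L]) * 180 / pi  # 0 = straight down
  depth <- sqrt((X - apex[1L])^2 + (Y - apex[2L])^2)
  sector <- abs(ang) <= spec$sector_angle / 2 & depth <= 0.95 & Y > apex[2L]

  cavity_center <- c(0.5, 0.42)
  cavity_axes <- c(0.16, 0.26)
  wall <- 0.09

  region_template <- function(displacement) {
    ca <- pmax(cavity_axes - displacement, 0.01)
    cav <- inside_ellipse(X, Y, cavity_center, ca)
    myo <- inside_ellipse(X, Y, cavity_center, ca + wall) & !cav
    tmpl <- matrix(spec$background_mean, h, w)
    tmpl[myo] <- spec$myocardium_mean
    tmpl[cav] <- spec$cavity_mean
    thr <- NULL
    if (!is.null(spec$thrombus)) {
      thr <- inside_ellipse(X, Y, spec$thrombus$center, spec$thrombus$axes) &
        cav
      tmpl[thr] <- spec$thrombus_mean
    }
    tmpl[!sector] <- 0
    list(template = tmpl, cavity = cav, myocardium = myo, thrombus = thr)
  }

  base <- region_template(0)
  frames <- with_seed(spec$seed, lapply(seq_len(spec$n_frames), function(t) {
    disp <- spec$motion_amplitude * sin(2 * pi * (t - 1) / spec$n_frames)
    tmpl <- region_template(disp)$template
    e <- matrix(stats::rexp(h * w), h, w)  # |circular Gaussian|^2, mean 1
    speckle <- 1 + spec$speckle_scale * (conv3x3(e, PSF_KERNEL) - 1)
    quantize_8bit(pmin(pmax(tmpl * pmax(speckle, 0), 0), 1))
  }))

  thr_mask <- if (is.null(base$thrombus)) matrix(FALSE, h, w) else
    base$thrombus
  list(loop = cine_loop(frames, frame_rate = 30,
                        source_format = "synthetic"),
       masks = list(sector = sector,
                    cavity = base$cavity & !thr_mask,
                    myocardium = base$myocardium,
                    thrombus = thr_mask))
}

#' Contrast-to-noise ratio between two regions of a cine loop
#'
#' `|mean(a) - mean(b)| / sd(b)` over the pixels of the two masks pooled
#' across all frames. Region `b` is the noise reference (typically the
#' cavity). If region `b` is constant the ratio is undefined and `NA` is
#' returned with a warning.
#'
#' @param loop A [cine_loop()] or a list of numeric frames.
#' @param mask_a,mask_b Logical matrices matching the frame dimensions;
#'   must be non-empty and disjoint.
#' @return A single number (gray levels of `a`-to-`b` separation per gray
#'   level of `b` noise), or `NA` if undefined.
#' @export
measure_cnr <- function(loop, mask_a, mask_b) {
  frames <- if (inherits(loop, "cine_loop")) loop$frames else loop
  if (!any(mask_a) || !any(mask_b))
    stop("region masks must be non-empty")
  if (any(mask_a & mask_b))
    stop("region masks must be disjoint")
  va <- unlist(lapply(frames, function(f) f[mask_a]), use.names = FALSE)
  vb <- unlist(lapply(frames, function(f) f[mask_b]), use.names = FALSE)
  sb <- stats::sd(vb)
  if (!is.finite(sb) || sb == 0) {
    warning("reference region is constant: CNR is undefined")
    return(NA_real_)
  }
  abs(mean(va) - mean(vb)) / sb
}
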