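# Synthetic vessel phantoms with known centerline and width.
#
# Phantoms emulate the hand-labeled fundus vessel maps the pipeline
# consumes: bright tubes on a dark background, rendered with
# coverage-fraction anti-aliasing so the true edge has a subpixel position,
# plus optional seeded Gaussian noise. The analytic centerline and the
# width profile are returned as ground truth for recovery tests.

#' Specify a synthetic vessel phantom
#'
#' @param shape `"straight"`, `"sinusoidal"`, `"tapering"` or
#'   `"bifurcation"`.
#' @param image_size `(height, width)` in pixels.
#' @param width_px True vessel width in pixels. For `"tapering"` a length-2
#'   vector `(start, end)`; for `"bifurcation"` a length-3 vector of arm
#'   widths.
#' @param orientation_deg Centerline angle in degrees (0 = horizontal,
#'   measured counterclockwise in the (row, col) frame with rows downward).
#' @param amplitude,period Sinusoid amplitude and period in pixels
#'   (sinusoidal shape only).
#' @param vessel_intensity,background_intensity Grayscale levels in
#'   `[0, 1]`; defaults 0.85 / 0.15 mimic a hand-labeled map (bright
#'   vessels on a dark fundus).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = none).
#' @param antialias Render edges with coverage-fraction anti-aliasing
#'   (default `TRUE`); `FALSE` gives a hard binary edge.
#' @param seed RNG seed fixing the noise (ignored when `noise_sd = 0`).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("straight", "sinusoidal", "tapering",
                                   "bifurcation"),
                         image_size = c(160L, 160L),
                         width_px = 8,
                         orientation_deg = 0,
                         amplitude = 5, period = 80,
                         vessel_intensity = 0.85,
                         background_intensity = 0.15,
                         noise_sd = 0,
                         antialias = TRUE,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (any(width_px < 1)) stop("`width_px` must be >= 1", call. = FALSE)
  if (shape == "tapering" && length(width_px) != 2L)
    stop("tapering phantoms need width_px = c(start, end)", call. = FALSE)
  if (shape == "bifurcation" && length(width_px) != 3L)
    stop("bifurcation phantoms need three arm widths", call. = FALSE)
  if (vessel_intensity < 0 || vessel_intensity > 1 ||
      background_intensity < 0 || background_intensity > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(shape = shape, image_size = as.integer(image_size),
                 width_px = width_px, orientation_deg = orientation_deg,
                 amplitude = amplitude, period = period,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, antialias = antialias,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic vessel phantom with ground truth
#'
#' Renders the tube specified by `spec` and returns the image together with
#' the analytic centerline, the width profile along it, and the true binary
#' vessel mask (pixels within half the local width of the centerline).
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (grayscale matrix), `truth` (list with
#'   `centerline` n x 2 subpixel polyline, `width_at` numeric vector of
#'   local widths matching `centerline` rows, `mask` 0/1 matrix), and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec("straight", width_px = 8))
#' range(ph$image)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$shape == "bifurcation") return(generate_bifurcation_phantom(spec))

  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  margin <- 6 + max(spec$width_px) / 2
  half_len <- tube_half_length(h, w, spec$orientation_deg, margin)
  if (half_len <= max(spec$width_px))
    stop("vessel does not fit in the image at this orientation",
         call. = FALSE)

  # arc-length parameter t in [-half_len, half_len], sampled at 0.25 px
  t <- seq(-half_len, half_len, by = 0.25)
  th <- spec$orientation_deg * pi / 180
  dir <- c(-sin(th), cos(th))          # (row, col); rows grow downward
  nrm <- c(-cos(th), -sin(th))
  base_r <- ctr[1L] + t * dir[1L]
  base_c <- ctr[2L] + t * dir[2L]
  if (spec$shape == "sinusoidal") {
    dev <- spec$amplitude * sin(2 * pi * t / spec$period)
    cl <- cbind(base_r + dev * nrm[1L], base_c + dev * nrm[2L])
  } else {
    cl <- cbind(base_r, base_c)
  }
  width_at <- if (spec$shape == "tapering") {
    spec$width_px[1L] + (t + half_len) / (2 * half_len) *
      (spec$width_px[2L] - spec$width_px[1L])
  } else {
    rep(spec$width_px[1L], length(t))
  }
  if (any(cl[, 1L] < 1 + width_at / 2) || any(cl[, 1L] > h - width_at / 2) ||
      any(cl[, 2L] < 1 + width_at / 2) || any(cl[, 2L] > w - width_at / 2))
    stop("vessel exceeds image bounds", call. = FALSE)

  band <- rasterize_band(h, w, cl, width_at)
  finish_phantom(band, cl, width_at, spec)
}

#' Generate a Y-junction phantom
#'
#' Three straight tubes of given widths meeting at a junction point; truth
#' includes the junction coordinate and each arm's centerline.
#'
#' @param spec A [phantom_spec()] with `shape = "bifurcation"` and three
#'   arm widths; `orientation_deg` rotates the whole Y.
#' @param arm_angles_deg Directions of the three arms (degrees).
#' @param arm_length Arm length in pixels; default fills the image to a
#'   6-px margin.
#' @return As [generate_phantom()], with `truth$junction` (row, col) and
#'   `truth$arms` (list of per-arm centerline/width).
#' @export
generate_bifurcation_phantom <- function(spec,
                                         arm_angles_deg = c(90, 210, 330),
                                         arm_length = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$width_px) != 3L)
    stop("bifurcation phantoms need three arm widths", call. = FALSE)
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  if (is.null(arm_length))
    arm_length <- min(h, w) / 2 - 6 - max(spec$width_px) / 2
  if (arm_length <= 0) stop("zero-length arm", call. = FALSE)

  arms <- list()
  cover <- matrix(0, h, w)
  maskm <- matrix(0, h, w)
  for (i in 1:3) {
    th <- (arm_angles_deg[i] + spec$orientation_deg) * pi / 180
    dir <- c(-sin(th), cos(th))
    t <- seq(0, arm_length, by = 0.25)
    cl <- cbind(ctr[1L] + t * dir[1L], ctr[2L] + t * dir[2L])
    if (any(cl < 1) || any(cl[, 1L] > h) || any(cl[, 2L] > w))
      stop("vessel exceeds image bounds", call. = FALSE)
    wa <- rep(spec$width_px[i], length(t))
    b <- rasterize_band(h, w, cl, wa, flat_start = FALSE)
    cover <- pmax(cover, b$coverage)
    maskm <- pmax(maskm, b$mask)
    arms[[i]] <- list(centerline = cl, width_at = wa)
  }
  out <- finish_phantom(list(coverage = cover, mask = maskm),
                        arms[[1L]]$centerline, arms[[1L]]$width_at, spec)
  out$truth$junction <- ctr
  out$truth$arms <- arms
  out
}

# Half-length of a tube through the image center at the given angle that
# stays `margin` px away from every border.
tube_half_length <- function(h, w, angle_deg, margin) {
  th <- angle_deg * pi / 180
  dr <- abs(sin(th)); dc <- abs(cos(th))
  lim_r <- if (dr > 1e-12) ((h - 1) / 2 - margin) / dr else Inf
  lim_c <- if (dc > 1e-12) ((w - 1) / 2 - margin) / dc else Inf
  min(lim_r, lim_c)
}

# Rasterize a band of local half-width width_at/2 around a fine polyline.
# Returns per-pixel coverage in [0, 1] (linear edge model: full at
# d <= w/2 - 0.5, zero at d >= w/2 + 0.5) and the exact binary mask
# (d <= w/2). Ends are cut flat (a vessel crossing the field of view, not
# a capsule): pixels beyond the end planes are cleared unless the
# corresponding `flat_*` flag is FALSE (used for bifurcation arms whose
# start merges into the junction).
rasterize_band <- function(h, w, cl, width_at, flat_start = TRUE,
                           flat_end = TRUE) {
  dist <- matrix(Inf, h, w)
  wloc <- matrix(0, h, w)
  maxw <- max(width_at)
  # per-sample local window update of the distance field
  for (i in seq_len(nrow(cl))) {
    r0 <- cl[i, 1L]; c0 <- cl[i, 2L]
    hw <- width_at[i] / 2 + 1.5
    rs <- max(1L, floor(r0 - hw)):min(h, ceiling(r0 + hw))
    cs <- max(1L, floor(c0 - hw)):min(w, ceiling(c0 + hw))
    dd <- outer((rs - r0)^2, (cs - c0)^2, "+")
    sub <- dist[rs, cs, drop = FALSE]
    upd <- dd < sub^2
    if (any(upd)) {
      sub[upd] <- sqrt(dd[upd])
      dist[rs, cs] <- sub
      wl <- wloc[rs, cs, drop = FALSE]
      wl[upd] <- width_at[i]
      wloc[rs, cs] <- wl
    }
  }
  coverage <- pmin(pmax(wloc / 2 + 0.5 - dist, 0), 1)
  mask <- (dist <= wloc / 2) * 1

  clip_end <- function(e, u, hw) {
    rs <- max(1L, floor(e[1L] - hw)):min(h, ceiling(e[1L] + hw))
    cs <- max(1L, floor(e[2L] - hw)):min(w, ceiling(e[2L] + hw))
    along <- outer((rs - e[1L]) * u[1L], (cs - e[2L]) * u[2L], "+")
    out <- along < 0            # beyond the end plane, away from the tube
    subc <- coverage[rs, cs, drop = FALSE]; subc[out] <- 0
    coverage[rs, cs] <<- subc
    subm <- mask[rs, cs, drop = FALSE]; subm[out] <- 0
    mask[rs, cs] <<- subm
  }
  n <- nrow(cl)
  hw_clip <- max(width_at) / 2 + 2
  if (flat_start) {
    u <- cl[2L, ] - cl[1L, ]; u <- u / sqrt(sum(u^2))
    clip_end(cl[1L, ], u, hw_clip)
  }
  if (flat_end) {
    u <- cl[n - 1L, ] - cl[n, ]; u <- u / sqrt(sum(u^2))
    clip_end(cl[n, ], u, hw_clip)
  }
  list(coverage = coverage, mask = mask)
}

finish_phantom <- function(band, centerline, width_at, spec) {
  cov <- if (spec$antialias) band$coverage else band$mask
  img <- spec$background_intensity +
    (spec$vessel_intensity - spec$background_intensity) * cov
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed,
      matrix(stats::rnorm(length(img), 0, spec$noise_sd),
             nrow(img), ncol(img)))
    img <- pmin(pmax(img, 0), 1)
  }
  colnames(centerline) <- NULL
  list(image = img,
       truth = list(centerline = centerline, width_at = width_at,
                    mask = band$mask),
       spec = spec)
}
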