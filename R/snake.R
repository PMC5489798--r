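# Active-contour (snake) vessel edge detection.
#
# The snake is an ordered set of contour points v(s) = (row(s), col(s))
# minimizing E = E_cont + E_curv + E_ext, where the continuity term
# penalizes stretching (first difference of v), the curvature term
# penalizes bending (second difference), and the external term
# -gamma * |grad(G_sigma * I)|^2 pulls the contour onto image edges.
# Minimization is a greedy discrete local search: every sweep moves each
# point to the lowest-energy position in its local neighborhood, so the
# total energy never increases within a sweep sequence; evolution runs the
# external field through a coarse-to-fine sequence of Gaussian scales so an
# initialization several pixels away from the edge is still captured, then
# polishes at subpixel steps.

#' Snake parameters
#'
#' @param alpha Elasticity weight of the continuity energy (dimensionless).
#' @param beta Rigidity weight of the curvature energy.
#' @param gamma Weight of the external (image gradient) energy.
#' @param sigma Gaussian scale of the external field, pixels.
#' @param max_iterations Sweep budget per scale level.
#' @param search_radius Half-width of the candidate neighborhood, pixels.
#' @param continuity `"raw"` penalizes the squared first difference
#'   `|v_s|^2` directly (the textbook functional; contracts the contour
#'   onto the vessel); `"mean_spacing"` penalizes deviation from the mean
#'   point spacing (prevents point clustering, no contraction pressure).
#' @param sigma_levels Multipliers applied to `sigma` for coarse-to-fine
#'   evolution, coarse first; `1` must be last. A single level `1` evolves
#'   at `sigma` only.
#' @param refine_steps Subpixel step sizes appended at the finest level
#'   (after integer-step convergence).
#' @param normalize_external Scale `|grad|^2` by its maximum before
#'   weighting by `gamma`, so `gamma` is comparable with `alpha`/`beta`
#'   across images (default `TRUE`).
#' @param resample_spacing Target contour point spacing at each level,
#'   pixels.
#' @return A `snake_params` list.
#' @export
snake_params <- function(alpha = 0.01, beta = 0.005, gamma = 2, sigma = 1,
                         max_iterations = 200L, search_radius = 1L,
                         continuity = c("raw", "mean_spacing"),
                         sigma_levels = c(8, 4, 2, 1),
                         refine_steps = c(0.5, 0.25),
                         normalize_external = TRUE,
                         resample_spacing = 1.5) {
  continuity <- match.arg(continuity)
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, sigma >= 0,
            max_iterations >= 1, search_radius >= 1,
            all(sigma_levels > 0), resample_spacing > 0)
  sigma_levels <- sort(unique(c(sigma_levels, 1)), decreasing = TRUE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
                 max_iterations = as.integer(max_iterations),
                 search_radius = as.integer(search_radius),
                 continuity = continuity, sigma_levels = sigma_levels,
                 refine_steps = refine_steps,
                 normalize_external = isTRUE(normalize_external),
                 resample_spacing = resample_spacing),
            class = "snake_params")
}

#' Construct a snake contour object
#'
#' @param points n x 2 `(row, col)` matrix, `n >= 3`.
#' @param closed Is the contour a closed loop?
#' @return A `snake_contour` with empty energy trace.
#' @export
snake_contour <- function(points, closed = TRUE) {
  pts <- as_points(points)
  if (nrow(pts) < 3L)
    stop("a snake contour needs at least 3 points", call. = FALSE)
  structure(list(points = pts, closed = isTRUE(closed),
                 energy_trace = list(), sweeps = 0L),
            class = "snake_contour")
}

#' External snake energy field of an image
#'
#' Computes `-gamma * |grad(G_sigma * I)|^2` on the pixel grid: the image
#' is convolved with a Gaussian kernel of scale `sigma`, the gradient is
#' taken by central differences, and the squared magnitude is weighted by
#' `-gamma` so that edges are energy minima. The field is everywhere
#' `<= 0`. Subpixel queries during evolution use bilinear interpolation.
#'
#' @param image Grayscale matrix.
#' @param sigma Gaussian scale in pixels (0 = no smoothing).
#' @param gamma External weight (>= 0).
#' @param normalize Divide `|grad|^2` by its maximum first (default
#'   `TRUE`), making the field range `[-gamma, 0]` independent of image
#'   contrast.
#' @return Matrix of the same shape as `image`.
#' @export
external_energy_field <- function(image, sigma, gamma, normalize = TRUE) {
  assert_gray(image)
  stopifnot(sigma >= 0, gamma >= 0)
  if (gamma == 0) return(matrix(0, nrow(image), ncol(image)))
  sm <- if (sigma > 0) {
    t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(image)),
                                        sigma = sigma)))
  } else image
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2
  gc <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2
  g2 <- gr^2 + gc^2
  if (normalize) {
    m <- max(g2)
    if (m > 0) g2 <- g2 / m
  }
  -gamma * g2
}

#' Internal energy terms at one contour point
#'
#' Evaluates the continuity and curvature energies of point `index`:
#' `e_cont = alpha * |v_s|^2` (raw form) or
#' `alpha * (dbar - |v_i - v_(i-1)|)^2` (mean-spacing form, `dbar` the mean
#' point spacing), and `e_curv = beta * |v_(i-1) - 2 v_i + v_(i+1)|^2`.
#' Terms without the required neighbors (open-contour ends) are zero.
#'
#' @param contour A [snake_contour()].
#' @param index Point index, 1-based.
#' @param params A [snake_params()].
#' @return Named numeric `c(e_cont, e_curv)`, both `>= 0`.
#' @export
internal_energy <- function(contour, index, params = snake_params()) {
  stopifnot(inherits(contour, "snake_contour"))
  pts <- contour$points
  n <- nrow(pts)
  if (!is.numeric(index) || index < 1 || index > n)
    stop("`index` out of range", call. = FALSE)
  i <- as.integer(index)
  prv <- if (i > 1L) i - 1L else if (contour$closed) n else NA_integer_
  nxt <- if (i < n) i + 1L else if (contour$closed) 1L else NA_integer_

  e_cont <- 0
  if (!is.na(prv)) {
    d <- sqrt(sum((pts[i, ] - pts[prv, ])^2))
    e_cont <- if (params$continuity == "mean_spacing") {
      params$alpha * (mean_spacing(pts, contour$closed) - d)^2
    } else {
      params$alpha * d^2
    }
  }
  e_curv <- 0
  if (!is.na(prv) && !is.na(nxt)) {
    vss <- pts[prv, ] - 2 * pts[i, ] + pts[nxt, ]
    e_curv <- params$beta * sum(vss^2)
  }
  c(e_cont = unname(e_cont), e_curv = unname(e_curv))
}

mean_spacing <- function(pts, closed) {
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                     pts[-nrow(pts), , drop = FALSE])^2))
  if (closed) d <- c(d, sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2)))
  mean(d)
}

#' Evolve a snake contour on an image
#'
#' Greedy minimization of the snake energy: for each Gaussian scale in
#' `params$sigma_levels * params$sigma` (coarse to fine), the external
#' field is recomputed, the contour resampled to uniform spacing, and
#' sweeps of local search run until no point moves or the iteration budget
#' is reached; the finest level appends subpixel refinement steps. Within
#' every level the recorded total energy is non-increasing by construction.
#'
#' @param init A [snake_contour()] (or n x 2 point matrix, treated as a
#'   closed contour) lying within the image bounds.
#' @param image Grayscale matrix (use the binary mask to run the snake on
#'   the segmentation instead of the intensities).
#' @param params A [snake_params()].
#' @return A `snake_contour` with final `points`, `energy_trace` (a list of
#'   per-level numeric vectors, each non-increasing) and total `sweeps`.
#' @export
evolve_snake <- function(init, image, params = snake_params()) {
  if (!inherits(init, "snake_contour")) init <- snake_contour(init)
  assert_gray(image)
  pts <- init$points
  if (any(pts[, 1L] < 1) || any(pts[, 1L] > nrow(image)) ||
      any(pts[, 2L] < 1) || any(pts[, 2L] > ncol(image)))
    stop("initial contour lies outside the image bounds", call. = FALSE)

  traces <- list()
  sweeps <- 0L
  levels <- params$sigma_levels * params$sigma
  if (params$sigma == 0) levels <- 0
  for (k in seq_along(levels)) {
    pts <- resample_polyline(pts, params$resample_spacing,
                             closed = init$closed)
    if (nrow(pts) < 3L)
      stop("contour degenerated below 3 points", call. = FALSE)
    field <- external_energy_field(image, levels[k], params$gamma,
                                   params$normalize_external)
    steps <- if (k == length(levels)) c(1, params$refine_steps) else 1
    res <- snake_greedy_cpp(pts, field, params$alpha, params$beta,
                            params$continuity == "mean_spacing",
                            init$closed, as.numeric(steps),
                            params$max_iterations, params$search_radius)
    pts <- res$points
    colnames(pts) <- c("row", "col")
    traces[[k]] <- res$trace
    sweeps <- sweeps + res$sweeps
  }
  structure(list(points = pts, closed = init$closed,
                 energy_trace = traces, sweeps = sweeps),
            class = "snake_contour")
}

#' Initialize a closed contour around a vessel branch
#'
#' Builds the starting snake for one vessel: the connected foreground
#' component of the segmentation mask containing the branch is dilated
#' outward by `margin` pixels (Euclidean distance threshold), its 0.5-level
#' boundary is extracted as a closed subpixel loop, and the loop is
#' resampled to uniform spacing. Other components of the mask (disjoint
#' vessels) are not enclosed.
#'
#' @param mask 0/1 segmentation mask.
#' @param branch A branch from [trace_branches()] (or an n x 2 point matrix
#'   of centerline pixels inside the mask).
#' @param margin Outward offset in pixels (default 2); 0 places the
#'   contour on the mask boundary itself.
#' @param spacing Contour point spacing after resampling.
#' @return A closed [snake_contour()].
#' @export
initialize_vessel_contour <- function(mask, branch, margin = 2,
                                      spacing = 1.5) {
  assert_binary(mask)
  stopifnot(margin >= 0)
  pts <- if (is.list(branch)) branch$points else branch
  pts <- as_points(pts)
  if (nrow(pts) == 0L) stop("branch region is empty", call. = FALSE)
  ipts <- round(pts)
  inside <- mask[cbind(ipts[, 1L], ipts[, 2L])] == 1
  if (!any(inside))
    stop("branch does not lie in the mask foreground", call. = FALSE)

  comp <- connected_component(mask, ipts[which(inside)[1L], ])
  region <- if (margin > 0) {
    bg <- EBImage::distmap(EBImage::Image(t(1 - comp)))
    comp_dil <- comp
    comp_dil[t(EBImage::imageData(bg)) <= margin] <- 1
    comp_dil
  } else comp

  # pad so components touching the border still yield closed level curves
  nr <- nrow(region); nc <- ncol(region)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- region
  loops <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                   z = padded, levels = 0.5)
  if (!length(loops)) stop("branch region is empty", call. = FALSE)

  mid <- pts[ceiling(nrow(pts) / 2), ]
  enclosing <- Filter(function(l) point_in_polygon(mid, cbind(l$x, l$y)),
                      loops)
  if (!length(enclosing)) enclosing <- loops
  areas <- vapply(enclosing, function(l)
    abs(shoelace_area(cbind(l$x, l$y))), numeric(1))
  loop <- enclosing[[which.max(areas)]]

  out <- cbind(row = loop$x, col = loop$y)
  if (nrow(out) > 1L && all(out[1L, ] == out[nrow(out), ]))
    out <- out[-nrow(out), , drop = FALSE]
  if (shoelace_area(out[, c(2L, 1L)]) < 0)   # counterclockwise in (x, y)
    out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  out <- resample_polyline(out, spacing, closed = TRUE)
  out[, 1L] <- pmin(pmax(out[, 1L], 1), nrow(mask))
  out[, 2L] <- pmin(pmax(out[, 2L], 1), ncol(mask))
  snake_contour(out, closed = TRUE)
}

# 8-connected component of `mask` containing pixel `seed` (row, col)
connected_component <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0, nr, nc)
  if (mask[seed[1L], seed[2L]] != 1) return(comp)
  stack <- matrix(as.integer(seed), 1L)
  comp[seed[1L], seed[2L]] <- 1
  while (nrow(stack)) {
    p <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    rs <- max(1L, p[1L] - 1L):min(nr, p[1L] + 1L)
    cs <- max(1L, p[2L] - 1L):min(nc, p[2L] + 1L)
    for (r in rs) for (cc in cs) {
      if (mask[r, cc] == 1 && comp[r, cc] == 0) {
        comp[r, cc] <- 1
        stack <- rbind(stack, c(r, cc))
      }
    }
  }
  comp
}

# signed shoelace area of an (x, y) polygon
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

# even-odd rule point-in-polygon; p = (a, b) tested against poly columns 1, 2
point_in_polygon <- function(p, poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > p[2L]) != (y[j] > p[2L]) &&
        p[1L] < (x[j] - x[i]) * (p[2L] - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Resample a polyline to uniform arc-length spacing
#'
#' @param pts n x 2 point matrix.
#' @param spacing Target spacing in pixels.
#' @param closed Treat the polyline as a closed loop.
#' @return Resampled n' x 2 matrix (n' >= 3 for closed loops).
#' @export
resample_polyline <- function(pts, spacing, closed = FALSE) {
  pts <- as_points(pts)
  if (closed) pts <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg == 0)) {   # drop duplicate consecutive points
    keep <- c(TRUE, seg > 0)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2L) return(pts)
    seg <- seg[seg > 0]
  }
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total == 0) return(pts[1L, , drop = FALSE])
  n_out <- max(if (closed) 4L else 2L, round(total / spacing))
  s <- if (closed) seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
       else seq(0, total, length.out = n_out)
  cbind(row = stats::approx(arc, pts[, 1L], xout = s)$y,
        col = stats::approx(arc, pts[, 2L], xout = s)$y)
}
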