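# Vessel diameter from characteristic points and contour points.
#
# For a chord between two consecutive characteristic points N and P on the
# centerline, one contour point is chosen on each side of the line NP. Each
# (N, P, M) triangle's side lengths give its area by Heron's formula, and
# the height from M onto NP is h = 2A / |NP|. The local vessel diameter is
# the sum of the two heights from the opposite-side contour points.

#' Euclidean side lengths of the measurement triangle
#'
#' @param N,P Characteristic-point coordinates `(row, col)`.
#' @param M Contour-point coordinate `(row, col)`.
#' @return Numeric `c(a, b, c)` with `a = |NP|`, `b = |MP|`, `c = |NM|`.
#' @examples
#' side_lengths(c(0, 0), c(3, 4), c(0, 4))
#' @export
side_lengths <- function(N, P, M) {
  N <- as.numeric(N); P <- as.numeric(P); M <- as.numeric(M)
  c(a = sqrt(sum((N - P)^2)),
    b = sqrt(sum((M - P)^2)),
    c = sqrt(sum((N - M)^2)))
}

#' Triangle area by Heron's formula
#'
#' `A = sqrt(S (S - a)(S - b)(S - c))` with `S = (a + b + c) / 2` the half
#' perimeter. A radicand that is negative by no more than `tol` (floating
#' point near-degeneracy) is clamped to zero; a grosser triangle-inequality
#' violation is an error.
#'
#' @param a,b,c Side lengths (>= 0).
#' @param tol Clamping tolerance for the radicand (default `1e-9`).
#' @return Area in pixels squared.
#' @examples
#' heron_area(3, 4, 5)  # 6
#' @export
heron_area <- function(a, b, c, tol = 1e-9) {
  sides <- c(a, b, c)
  if (any(!is.finite(sides)) || any(sides < 0))
    stop("side lengths must be finite and non-negative", call. = FALSE)
  S <- (a + b + c) / 2
  rad <- S * (S - a) * (S - b) * (S - c)
  if (rad < -tol * max(1, S^4))
    stop(sprintf(
      "sides (%g, %g, %g) grossly violate the triangle inequality", a, b, c),
      call. = FALSE)
  sqrt(max(rad, 0))
}

#' Triangle height over a given base
#'
#' Inverts `A = h * a / 2` to `h = 2 A / a`. For the measurement triangle
#' this equals the perpendicular distance from the contour point to the
#' characteristic chord.
#'
#' @param A Triangle area (pixels^2).
#' @param a Base length (> 0).
#' @return Height in pixels.
#' @examples
#' triangle_height(6, 5)  # 2.4
#' @export
triangle_height <- function(A, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("base length `a` must be positive", call. = FALSE)
  unname(2 * A / a)
}

#' Select one contour point on each side of a characteristic chord
#'
#' The side of a contour point M relative to the directed line N->P is the
#' sign of the cross product (P - N) x (M - N). Among the candidates whose
#' perpendicular foot falls within the segment NP, the point whose foot is
#' nearest the segment midpoint is chosen per side; a side with no
#' in-segment foot falls back to the point whose foot is nearest the
#' segment. If one side has no points at all, that side is `NULL` and the
#' caller is expected to skip the measurement.
#'
#' @param N,P Characteristic points `(row, col)`, distinct.
#' @param contour A snake contour (see [evolve_snake()]) or an n x 2 point
#'   matrix.
#' @return List with `M_up`, `M_down` (coordinate pairs or `NULL`).
#' @export
select_contour_points <- function(N, P, contour) {
  pts <- contour_points(contour)
  N <- as.numeric(N); P <- as.numeric(P)
  if (all(N == P)) stop("N and P must be distinct", call. = FALSE)
  d <- P - N
  len2 <- sum(d^2)
  rel_r <- pts[, 1L] - N[1L]; rel_c <- pts[, 2L] - N[2L]
  cross <- d[1L] * rel_c - d[2L] * rel_r
  tfoot <- (d[1L] * rel_r + d[2L] * rel_c) / len2

  pick_side <- function(on_side) {
    idx <- which(on_side)
    if (!length(idx)) return(NULL)
    t <- tfoot[idx]
    inseg <- t >= 0 & t <= 1
    if (any(inseg)) {
      cand <- idx[inseg]
      cand[which.min(abs(tfoot[cand] - 0.5))]
    } else {
      # distance of the foot beyond the segment ends
      over <- pmax(-t, t - 1)
      idx[which.min(over)]
    }
  }
  up <- pick_side(cross > 0)
  down <- pick_side(cross < 0)
  if (is.null(up) || is.null(down))
    warning("contour lies entirely on one side of the chord NP",
            call. = FALSE)
  list(M_up = if (is.null(up)) NULL else pts[up, ],
       M_down = if (is.null(down)) NULL else pts[down, ])
}

#' Measure the vessel diameter across one characteristic chord
#'
#' Builds the two triangles (N, P, M_up) and (N, P, M_down) from
#' opposite-side contour points, computes each height from the contour
#' point onto the chord via Heron's formula, and reports the diameter as
#' the sum of the two heights.
#'
#' @inheritParams select_contour_points
#' @return A list with `N`, `P`, `M_up`, `M_down`, `h1`, `h2`, `diameter`
#'   (pixels), or `NULL` when no opposite-side pair exists (with a warning).
#' @examples
#' contour <- rbind(c(4, 0), c(4, 40), c(-4, 40), c(-4, 0))
#' measure_segment(c(0, 10), c(0, 30), contour)$diameter  # 8
#' @export
measure_segment <- function(N, P, contour) {
  sel <- select_contour_points(N, P, contour)
  if (is.null(sel$M_up) || is.null(sel$M_down)) return(NULL)
  h_of <- function(M) {
    s <- side_lengths(N, P, M)
    triangle_height(heron_area(s[1L], s[2L], s[3L]), s[1L])
  }
  h1 <- unname(h_of(sel$M_up))
  h2 <- unname(h_of(sel$M_down))
  list(N = as.numeric(N), P = as.numeric(P),
       M_up = as.numeric(sel$M_up), M_down = as.numeric(sel$M_down),
       h1 = h1, h2 = h2, diameter = h1 + h2)
}

#' Measure diameters along a vessel branch
#'
#' Applies [measure_segment()] to each consecutive pair of characteristic
#' points, producing one diameter per chord.
#'
#' @param characteristic_points n x 2 matrix (`n >= 2`) of characteristic
#'   points in branch order, e.g. from [douglas_peucker()].
#' @param contour The snake contour of the same vessel.
#' @return A data frame with one row per chord: `segment_id`, `row_N`,
#'   `col_N`, `row_P`, `col_P`, `h1`, `h2`, `diameter`; skipped segments
#'   appear with `NA` measurements.
#' @export
measure_vessel <- function(characteristic_points, contour) {
  cp <- as_points(characteristic_points)
  if (nrow(cp) < 2L)
    stop("need at least 2 characteristic points", call. = FALSE)
  out <- lapply(seq_len(nrow(cp) - 1L), function(i) {
    m <- measure_segment(cp[i, ], cp[i + 1L, ], contour)
    data.frame(segment_id = i,
               row_N = cp[i, 1L], col_N = cp[i, 2L],
               row_P = cp[i + 1L, 1L], col_P = cp[i + 1L, 2L],
               h1 = if (is.null(m)) NA_real_ else m$h1,
               h2 = if (is.null(m)) NA_real_ else m$h2,
               diameter = if (is.null(m)) NA_real_ else m$diameter)
  })
  do.call(rbind, out)
}

# Accept a snake_contour or a bare point matrix.
contour_points <- function(contour) {
  if (inherits(contour, "snake_contour")) contour <- contour$points
  pts <- as_points(contour)
  if (nrow(pts) == 0L) stop("contour is empty", call. = FALSE)
  pts
}
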