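# Douglas-Peucker reduction of centerline curves to characteristic points,
# and the data-compression-ratio statistic.

#' Perpendicular distance from a point to a segment's supporting line
#'
#' Distance from `point` to the infinite line through `seg_start` and
#' `seg_end` (the construction the Douglas-Peucker split uses); computed as
#' |cross product| / base length. A degenerate segment falls back to the
#' point-to-point distance.
#'
#' @param point,seg_start,seg_end `(row, col)` coordinate pairs.
#' @return Non-negative distance in pixels.
#' @examples
#' perpendicular_distance(c(3, 5), c(0, 0), c(0, 10))  # 3
#' @export
perpendicular_distance <- function(point, seg_start, seg_end) {
  p <- as.numeric(point); a <- as.numeric(seg_start); b <- as.numeric(seg_end)
  ab <- b - a
  base <- sqrt(sum(ab^2))
  if (base == 0) return(sqrt(sum((p - a)^2)))
  abs(ab[1L] * (p[2L] - a[2L]) - ab[2L] * (p[1L] - a[1L])) / base
}

#' Douglas-Peucker polyline simplification
#'
#' Connects the end nodes of the curve with a chord, finds the curve point
#' farthest (perpendicular) from the chord, and, if that distance exceeds
#' the tolerance `epsilon`, splits the curve there and recurses on both
#' halves; points closer than `epsilon` are eliminated. The retained points
#' are the curve's characteristic points. Ties for the farthest point split
#' at the lower index.
#'
#' @param curve n x 2 `(row, col)` matrix, `n >= 2`, no two consecutive
#'   points identical.
#' @param epsilon Tolerance in pixels (> 0).
#' @return An ordered subset of the input rows, always containing both end
#'   nodes.
#' @examples
#' curve <- cbind(c(0, 3, 0), c(0, 5, 10))
#' douglas_peucker(curve, epsilon = 1)   # keeps the apex
#' douglas_peucker(curve, epsilon = 4)   # end nodes only
#' @export
douglas_peucker <- function(curve, epsilon) {
  curve <- as_points(curve)
  if (nrow(curve) < 2L)
    stop("`curve` must have at least 2 points", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("`epsilon` must be a positive scalar", call. = FALSE)

  n <- nrow(curve)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  # explicit stack instead of recursion (branches can be thousands of points)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    idx <- (i + 1L):(j - 1L)
    d <- seg_point_line_dist(curve[idx, , drop = FALSE],
                             curve[i, ], curve[j, ])
    kmax <- which.max(d)           # which.max returns the first (lowest) tie
    if (d[kmax] > epsilon) {
      split <- idx[kmax]
      keep[split] <- TRUE
      stack <- c(stack, list(c(i, split), c(split, j)))
    }
  }
  curve[keep, , drop = FALSE]
}

# vectorized point-to-line distance for all rows of `pts`
seg_point_line_dist <- function(pts, a, b) {
  ab <- b - a
  base <- sqrt(sum(ab^2))
  if (base == 0) return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  abs(ab[1L] * (pts[, 2L] - a[2L]) - ab[2L] * (pts[, 1L] - a[1L])) / base
}

#' Data compression ratio of a simplification
#'
#' Percentage of centerline points removed by Douglas-Peucker reduction:
#' `100 * (N_total - n_kept) / N_total`.
#'
#' @param N_total Input point count (>= 1).
#' @param n_kept Characteristic point count (1 <= n_kept <= N_total).
#' @return Percentage in `[0, 100)`.
#' @examples
#' compression_ratio(100, 8)   # 92
#' compression_ratio(1000, 34) # 96.6
#' @export
compression_ratio <- function(N_total, n_kept) {
  if (!is.numeric(N_total) || N_total < 1)
    stop("`N_total` must be >= 1", call. = FALSE)
  if (!is.numeric(n_kept) || n_kept < 1 || n_kept > N_total)
    stop("`n_kept` must be in [1, N_total]", call. = FALSE)
  100 * (N_total - n_kept) / N_total
}

#' Summarize a simplification as a compression report
#'
#' @param curve Original polyline (n x 2 matrix).
#' @param simplified Simplified polyline (subset of `curve`).
#' @return A list with `N_total`, `n_kept`, `dcr` (percent).
#' @export
compression_report <- function(curve, simplified) {
  N <- nrow(as_points(curve)); n <- nrow(as_points(simplified))
  list(N_total = N, n_kept = n, dcr = compression_ratio(N, n))
}
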