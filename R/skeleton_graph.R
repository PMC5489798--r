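# Skeleton-pixel classification and centerline branch tracing.
#
# A skeleton pixel is classified by the number of active pixels among its 8
# neighbors (a 3x3 sliding mask minus the center): 1 neighbor = endpoint,
# 2 = inner point, >2 = bifurcation point. Pixels with no active neighbor
# get an explicit "isolated" class and are excluded from measurement.

PIXEL_CLASSES <- c("isolated", "endpoint", "inner", "bifurcation")

# Count of active 8-neighbors for every pixel (matrix-valued).
neighbor_counts <- function(skeleton) {
  shift_mat(skeleton, -1,  0) + shift_mat(skeleton, -1,  1) +
  shift_mat(skeleton,  0,  1) + shift_mat(skeleton,  1,  1) +
  shift_mat(skeleton,  1,  0) + shift_mat(skeleton,  1, -1) +
  shift_mat(skeleton,  0, -1) + shift_mat(skeleton, -1, -1)
}

#' Classify one skeleton pixel by its 3x3 neighborhood
#'
#' @param skeleton 0/1 skeleton matrix.
#' @param coord `(row, col)` of a foreground pixel.
#' @return One of `"endpoint"` (exactly 1 active neighbor), `"inner"`
#'   (exactly 2), `"bifurcation"` (more than 2), `"isolated"` (none).
#' @examples
#' sk <- matrix(0, 5, 5); sk[3, 2:4] <- 1
#' classify_pixel(sk, c(3, 2))  # endpoint
#' classify_pixel(sk, c(3, 3))  # inner
#' @export
classify_pixel <- function(skeleton, coord) {
  assert_binary(skeleton)
  coord <- as.integer(coord)
  if (length(coord) != 2L || skeleton[coord[1L], coord[2L]] != 1)
    stop("`coord` must index a foreground skeleton pixel", call. = FALSE)
  n <- neighbor_counts(skeleton)[coord[1L], coord[2L]]
  if (n == 0) "isolated" else if (n == 1) "endpoint"
  else if (n == 2) "inner" else "bifurcation"
}

#' Detect endpoints, bifurcations and inner points of a skeleton
#'
#' Partitions every foreground pixel of a one-pixel-wide skeleton into the
#' four neighbor-count classes. The four coordinate sets are disjoint and
#' together cover the foreground exactly.
#'
#' @param skeleton 0/1 skeleton matrix.
#' @return A list with integer `(row, col)` matrices `endpoints`,
#'   `bifurcations`, `inner`, `isolated`, each ordered row-major.
#' @examples
#' sk <- matrix(0, 5, 12); sk[3, 2:11] <- 1
#' detect_points(sk)$endpoints
#' @export
detect_points <- function(skeleton) {
  assert_binary(skeleton)
  n <- neighbor_counts(skeleton)
  pick <- function(cond) {
    w <- which(skeleton == 1 & cond, arr.ind = TRUE)
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
    colnames(w) <- c("row", "col")
    w
  }
  list(endpoints    = pick(n == 1),
       bifurcations = pick(n > 2),
       inner        = pick(n == 2),
       isolated     = pick(n == 0))
}

#' Trace ordered centerline branches of a skeleton
#'
#' Walks the skeleton from terminal pixels (endpoints and bifurcation
#' pixels) through runs of inner pixels, producing one ordered polyline per
#' branch. Adjacent bifurcation pixels are merged into a single junction
#' cluster (thinning frequently leaves 2-pixel junctions) whose
#' representative is the pixel with the lowest row, then column. Pure
#' cycles with no terminal are emitted as closed branches with a warning.
#'
#' @param skeleton 0/1 skeleton matrix (one pixel wide).
#' @param min_length Drop branches with fewer than this many pixels
#'   (default 2, i.e. keep everything traceable).
#' @return A list of branches; each is a list with `points` (n x 2 integer
#'   `(row, col)` matrix, consecutive rows 8-adjacent), `start_kind`,
#'   `end_kind` (pixel classes of the terminals), and `closed` (logical).
#'   Branches are ordered by their terminal coordinates.
#' @examples
#' sk <- matrix(0, 7, 12); sk[4, 2:11] <- 1
#' length(trace_branches(sk))
#' @export
trace_branches <- function(skeleton, min_length = 2L) {
  assert_binary(skeleton)
  fg <- which(skeleton == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(list())
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  deg <- neighbor_counts(skeleton)

  key <- function(r, c) (c - 1L) * nr + r
  is_fg <- logical(nr * nc); is_fg[key(fg[, 1L], fg[, 2L])] <- TRUE
  degv <- integer(nr * nc); degv[key(fg[, 1L], fg[, 2L])] <-
    deg[cbind(fg[, 1L], fg[, 2L])]

  # fixed row-major neighbor scan order for determinism
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbors <- function(r, c) {
    rr <- r + offs[, 1L]; cc <- c + offs[, 2L]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    ok <- is_fg[key(rr, cc)]
    cbind(rr[ok], cc[ok])
  }

  # junction clusters: 8-connected groups of pixels with degree > 2
  cluster_id <- integer(nr * nc)   # 0 = not a junction
  junc <- fg[degv[key(fg[, 1L], fg[, 2L])] > 2L, , drop = FALSE]
  n_clusters <- 0L
  if (nrow(junc)) {
    junc <- junc[order(junc[, 1L], junc[, 2L]), , drop = FALSE]
    for (i in seq_len(nrow(junc))) {
      k <- key(junc[i, 1L], junc[i, 2L])
      if (cluster_id[k]) next
      n_clusters <- n_clusters + 1L
      queue <- matrix(junc[i, ], 1L)
      cluster_id[k] <- n_clusters
      while (nrow(queue)) {
        p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
        nb <- neighbors(p[1L], p[2L])
        for (j in seq_len(nrow(nb))) {
          kk <- key(nb[j, 1L], nb[j, 2L])
          if (degv[kk] > 2L && cluster_id[kk] == 0L) {
            cluster_id[kk] <- n_clusters
            queue <- rbind(queue, nb[j, ])
          }
        }
      }
    }
  }

  kind_of <- function(r, c) {
    d <- degv[key(r, c)]
    if (d == 0L) "isolated" else if (d == 1L) "endpoint"
    else if (d == 2L) "inner" else "bifurcation"
  }
  is_terminal <- function(r, c) degv[key(r, c)] != 2L

  # Walk from `from` into `into`, consuming inner pixels until a terminal.
  visited_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) {
    ka <- key(a[1L], a[2L]); kb <- key(b[1L], b[2L])
    paste0(min(ka, kb), "-", max(ka, kb))
  }
  inner_used <- logical(nr * nc)

  walk <- function(from, into) {
    pts <- rbind(from, into)
    prev <- from; cur <- into
    while (!is_terminal(cur[1L], cur[2L])) {
      if (cur[1L] == from[1L] && cur[2L] == from[2L]) break  # closed loop
      inner_used[key(cur[1L], cur[2L])] <<- TRUE
      nb <- neighbors(cur[1L], cur[2L])
      nxt <- nb[!(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]), ,
                drop = FALSE]
      if (nrow(nxt) == 0L) break        # safety: dead end
      prev <- cur; cur <- nxt[1L, ]
      pts <- rbind(pts, cur)
    }
    pts
  }

  terminals <- fg[degv[key(fg[, 1L], fg[, 2L])] != 2L &
                  degv[key(fg[, 1L], fg[, 2L])] != 0L, , drop = FALSE]
  terminals <- terminals[order(terminals[, 1L], terminals[, 2L]), ,
                         drop = FALSE]

  branches <- list()
  add_branch <- function(pts, closed = FALSE) {
    if (nrow(pts) < max(2L, min_length)) return()
    colnames(pts) <- c("row", "col")
    branches[[length(branches) + 1L]] <<- list(
      points = pts,
      start_kind = kind_of(pts[1L, 1L], pts[1L, 2L]),
      end_kind = kind_of(pts[nrow(pts), 1L], pts[nrow(pts), 2L]),
      closed = closed)
  }

  for (i in seq_len(nrow(terminals))) {
    t0 <- terminals[i, ]
    nb <- neighbors(t0[1L], t0[2L])
    for (j in seq_len(nrow(nb))) {
      n0 <- nb[j, ]
      # do not traverse within a junction cluster
      ck_t <- cluster_id[key(t0[1L], t0[2L])]
      ck_n <- cluster_id[key(n0[1L], n0[2L])]
      if (ck_t != 0L && ck_t == ck_n) next
      ek <- edge_key(t0, n0)
      if (!is.null(visited_edge[[ek]])) next
      pts <- walk(t0, n0)
      visited_edge[[ek]] <- TRUE
      last2 <- pts[nrow(pts) - c(1L, 0L), , drop = FALSE]
      visited_edge[[edge_key(last2[1L, ], last2[2L, ])]] <- TRUE
      add_branch(pts)
    }
  }

  # leftover cycles: inner pixels never consumed
  leftover <- fg[degv[key(fg[, 1L], fg[, 2L])] == 2L &
                 !inner_used[key(fg[, 1L], fg[, 2L])], , drop = FALSE]
  # exclude pixels already inside traced branches (interior bookkeeping
  # marks them; terminals of degree 2 cannot exist)
  if (nrow(leftover)) {
    seen <- new.env(hash = TRUE)
    for (b in branches)
      for (r in seq_len(nrow(b$points)))
        seen[[as.character(key(b$points[r, 1L], b$points[r, 2L]))]] <- TRUE
    keep <- vapply(seq_len(nrow(leftover)), function(r)
      is.null(seen[[as.character(key(leftover[r, 1L], leftover[r, 2L]))]]),
      logical(1L))
    leftover <- leftover[keep, , drop = FALSE]
  }
  while (nrow(leftover)) {
    start <- leftover[order(leftover[, 1L], leftover[, 2L])[1L], ]
    nb <- neighbors(start[1L], start[2L])
    pts <- walk(start, nb[1L, ])
    warning("skeleton contains a closed loop with no terminal point",
            call. = FALSE)
    add_branch(pts, closed = TRUE)
    done <- paste(pts[, 1L], pts[, 2L])
    keep <- !(paste(leftover[, 1L], leftover[, 2L]) %in% done)
    leftover <- leftover[keep, , drop = FALSE]
  }

  # deterministic order: by first then last terminal coordinate
  if (length(branches)) {
    ord <- order(vapply(branches, function(b) b$points[1L, 1L], numeric(1)),
                 vapply(branches, function(b) b$points[1L, 2L], numeric(1)),
                 vapply(branches, function(b) b$points[nrow(b$points), 1L],
                        numeric(1)),
                 vapply(branches, function(b) b$points[nrow(b$points), 2L],
                        numeric(1)))
    branches <- branches[ord]
  }
  branches
}

#' Trim junction-adjacent pixels from a branch
#'
#' Near a bifurcation the thinned centerline bends through the junction
#' bar, so chords anchored there cut across the crotch between two
#' daughter vessels and do not measure a cross-section of either. This
#' removes up to `trim` pixels from any branch end that terminates at a
#' bifurcation, keeping at least 2 points; endpoint-terminated ends are
#' left intact.
#'
#' @param branch A branch from [trace_branches()].
#' @param trim Maximum number of pixels to drop per bifurcation end
#'   (default 5).
#' @return The branch with its `points` shortened accordingly.
#' @export
trim_junction_pixels <- function(branch, trim = 5L) {
  stopifnot(is.list(branch), !is.null(branch$points), trim >= 0)
  pts <- branch$points
  n <- nrow(pts)
  drop_start <- if (identical(branch$start_kind, "bifurcation")) trim else 0L
  drop_end <- if (identical(branch$end_kind, "bifurcation")) trim else 0L
  if (n - drop_start - drop_end >= 2L) {
    branch$points <- pts[(1L + drop_start):(n - drop_end), , drop = FALSE]
  }
  branch
}

#' Write detected skeleton points to CSV
#'
#' @param points Result of [detect_points()].
#' @param path Output CSV path (`kind,row,col`).
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  rows <- do.call(rbind, lapply(names(points), function(k) {
    m <- points[[k]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(kind = k, row = m[, 1L], col = m[, 2L])
  }))
  if (is.null(rows)) rows <- data.frame(kind = character(), row = integer(),
                                        col = integer())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
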