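# Fixtures and independent oracles shared by the tests. Everything is
# generated in code at test time; no binary fixtures.

# Anti-aliased bright disc on a dark background.
disc_image <- function(n = 101, radius = 20, bg = 0.15, fg = 0.85) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  bg + (fg - bg) * pmin(pmax(radius + 0.5 - d, 0), 1)
}

circle_contour <- function(n = 101, radius = 30, npts = 120) {
  ctr <- (n + 1) / 2
  th <- seq(0, 2 * pi, length.out = npts + 1)[-1]
  snake_contour(cbind(ctr + radius * sin(th), ctr + radius * cos(th)))
}

# Random blob mask: thresholded smoothed noise (seeded).
random_blob_mask <- function(seed, n = 40) {
  withr::with_seed(seed, {
    noise <- matrix(stats::runif(n * n), n, n)
    sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(noise)),
                                              sigma = 2)))
    (sm > stats::quantile(sm, 0.75)) * 1
  })
}

# Independent 8-connected component count (igraph oracle).
count_components8 <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  if (nrow(w) == 0L) return(0L)
  key <- paste(w[, 1L], w[, 2L])
  lookup <- stats::setNames(seq_len(nrow(w)), key)
  edges <- integer(0)
  for (k in seq_len(nrow(w))) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- lookup[paste(w[k, 1L] + dr, w[k, 2L] + dc)]
      if (!is.na(nb) && nb > k) edges <- c(edges, k, nb)
    }
  }
  g <- igraph::make_empty_graph(n = nrow(w), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Brute-force recursive Douglas-Peucker reference, coded independently of
# the package implementation (plain recursion, its own distance formula).
dp_reference <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1L, ]; b <- pts[n, ]
  ab <- b - a
  dist_to_line <- function(p) {
    if (all(ab == 0)) return(sqrt(sum((p - a)^2)))
    abs(ab[1L] * (p[2L] - a[2L]) - ab[2L] * (p[1L] - a[1L])) /
      sqrt(sum(ab^2))
  }
  d <- vapply(2:(n - 1L), function(i) dist_to_line(pts[i, ]), numeric(1))
  k <- which.max(d)
  if (d[k] > eps) {
    left <- dp_reference(pts[1:(k + 1L), , drop = FALSE], eps)
    right <- dp_reference(pts[(k + 1L):n, , drop = FALSE], eps)
    rbind(left[-nrow(left), , drop = FALSE], right)
  } else {
    pts[c(1L, n), , drop = FALSE]
  }
}

# Random open polyline with no repeated consecutive points.
random_polyline <- function(n) {
  steps <- matrix(stats::runif(2 * (n - 1), -3, 3), ncol = 2)
  steps[abs(steps) < 1e-3] <- 0.5
  apply(rbind(stats::runif(2, 0, 10), steps), 2, cumsum)
}

# Mean absolute diameter error of the longest traced vessel in an image.
phantom_recovery_error <- function(image, true_width,
                                   config = pipeline_config()) {
  res <- run_pipeline(image, config)
  longest <- which.max(vapply(res$branches,
                              function(b) nrow(b$points), numeric(1)))
  d <- res$diameters$diameter[res$diameters$branch_id == longest]
  d <- d[!is.na(d)]
  mean(abs(d - true_width))
}
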