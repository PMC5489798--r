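# Triangle geometry and diameter measurement.

test_that("side lengths are Euclidean distances", {
  expect_equal(unname(side_lengths(c(0, 0), c(3, 4), c(0, 0))[1]), 5)
  expect_equal(unname(side_lengths(c(1, 1), c(1, 1), c(1, 1))), c(0, 0, 0))
  withr::with_seed(2, {
    for (i in 1:20) {
      N <- runif(2, -5, 5); P <- runif(2, -5, 5); M <- runif(2, -5, 5)
      s <- side_lengths(N, P, M)
      expect_equal(unname(s), c(
        sqrt((N[1] - P[1])^2 + (N[2] - P[2])^2),
        sqrt((M[1] - P[1])^2 + (M[2] - P[2])^2),
        sqrt((N[1] - M[1])^2 + (N[2] - M[2])^2)))
    }
  })
})

test_that("Heron area agrees with the cross-product oracle", {
  expect_equal(heron_area(3, 4, 5), 6)
  expect_equal(heron_area(2, 3, 5), 0)           # collinear
  expect_error(heron_area(1, 1, 5), "triangle inequality")
  withr::with_seed(4, {
    for (i in 1:200) {
      N <- runif(2, -20, 20); P <- runif(2, -20, 20); M <- runif(2, -20, 20)
      s <- side_lengths(N, P, M)
      oracle <- abs((P[1] - N[1]) * (M[2] - N[2]) -
                    (P[2] - N[2]) * (M[1] - N[1])) / 2
      expect_equal(heron_area(s[1], s[2], s[3]), oracle, tolerance = 1e-9)
    }
  })
})

test_that("triangle height inverts the area formula and equals the
           perpendicular distance", {
  expect_equal(triangle_height(6, 5), 2.4)
  expect_equal(triangle_height(0, 3), 0)
  expect_error(triangle_height(6, 0), "positive")
  withr::with_seed(6, {
    for (i in 1:50) {
      N <- runif(2, -20, 20); P <- runif(2, -20, 20); M <- runif(2, -20, 20)
      if (all(N == P)) next
      s <- side_lengths(N, P, M)
      h <- triangle_height(heron_area(s[1], s[2], s[3]), s[1])
      expect_equal(h, perpendicular_distance(M, N, P), tolerance = 1e-9)
    }
  })
})

test_that("contour points are selected on opposite sides near the chord
           midpoint", {
  # horizontal centerline chord, contour points at rows +-4
  contour <- rbind(c(4, 0), c(4, 15), c(4, 20), c(4, 40),
                   c(-4, 0), c(-4, 22), c(-4, 40))
  sel <- select_contour_points(c(0, 10), c(0, 30), contour)
  expect_equal(abs(sel$M_up[["row"]]), 4)
  expect_equal(abs(sel$M_down[["row"]]), 4)
  expect_true(sign(sel$M_up[["row"]]) != sign(sel$M_down[["row"]]))
  # feet nearest the midpoint col 20 win
  expect_equal(sort(c(sel$M_up[["col"]], sel$M_down[["col"]])), c(20, 22))

  # contour entirely on one side: warning and one NULL side
  oneside <- rbind(c(4, 5), c(4, 20), c(4, 35))
  expect_warning(sel1 <- select_contour_points(c(0, 10), c(0, 30), oneside),
                 "one side")
  expect_equal(sum(vapply(sel1, is.null, logical(1))), 1L)
  expect_error(select_contour_points(c(0, 0), c(0, 0), contour), "distinct")
})

test_that("measure_segment recovers a symmetric tube width", {
  contour <- rbind(c(4, 0), c(4, 20), c(4, 40), c(-4, 0), c(-4, 20),
                   c(-4, 40))
  m <- measure_segment(c(0, 10), c(0, 30), contour)
  expect_equal(m$h1, 4, tolerance = 1e-9)
  expect_equal(m$h2, 4, tolerance = 1e-9)
  expect_equal(m$diameter, 8, tolerance = 1e-9)
})

test_that("diameter is invariant to N/P swap and rigid motion", {
  withr::with_seed(8, {
    contour <- cbind(c(runif(10, 2, 5), runif(10, -5, -2)), runif(20, 0, 40))
  })
  N <- c(0, 10); P <- c(0, 30)
  d0 <- measure_segment(N, P, contour)$diameter
  expect_equal(measure_segment(P, N, contour)$diameter, d0,
               tolerance = 1e-9)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(7, -3)
  rot <- function(p) as.numeric(R %*% p + shift)
  contour_r <- t(apply(contour, 1, rot))
  d1 <- measure_segment(rot(N), rot(P), contour_r)$diameter
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("measure_vessel walks consecutive characteristic pairs", {
  cp <- rbind(c(0, 5), c(0, 20), c(0, 35))
  contour <- rbind(c(3, 0), c(3, 12), c(3, 27), c(3, 40),
                   c(-3, 0), c(-3, 13), c(-3, 28), c(-3, 40))
  res <- measure_vessel(cp, contour)
  expect_equal(nrow(res), 2L)
  expect_equal(res$segment_id, 1:2)
  expect_equal(res$diameter, c(6, 6), tolerance = 1e-9)
  expect_error(measure_vessel(cp[1, , drop = FALSE], contour), "at least 2")
})
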