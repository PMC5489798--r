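# Snake energies, evolution and contour initialization.

test_that("external energy field is zero for flat images or zero gamma", {
  flat <- matrix(0.4, 20, 20)
  expect_equal(external_energy_field(flat, 1, 1.5), matrix(0, 20, 20))
  withr::with_seed(3, img <- matrix(runif(400), 20, 20))
  expect_equal(external_energy_field(img, 1, 0), matrix(0, 20, 20))
  expect_true(all(external_energy_field(img, 1, 2) <= 0))
})

test_that("a vertical step edge attracts the field minimum to the edge", {
  img <- matrix(0.1, 30, 30); img[, 16:30] <- 0.9
  fld <- external_energy_field(img, 1, 1)
  # minimum along every interior row sits at the step between cols 15/16
  mins <- apply(fld[5:25, ], 1, which.min)
  expect_true(all(mins %in% 15:16))
  # independent finite-difference oracle on the smoothed image
  sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)), 1)))
  r <- 15; cc <- 10
  gr <- (sm[r + 1, cc] - sm[r - 1, cc]) / 2
  gc <- (sm[r, cc + 1] - sm[r, cc - 1]) / 2
  g2 <- external_energy_field(img, 1, 1, normalize = FALSE)
  expect_equal(g2[r, cc], -(gr^2 + gc^2), tolerance = 1e-12)
})

test_that("external energy field is translation-equivariant", {
  withr::with_seed(21, base <- matrix(runif(30 * 30), 30, 30))
  img1 <- matrix(0.5, 60, 60); img1[10:39, 10:39] <- base
  img2 <- matrix(0.5, 60, 60); img2[15:44, 13:42] <- base
  f1 <- external_energy_field(img1, 1, 1, normalize = FALSE)
  f2 <- external_energy_field(img2, 1, 1, normalize = FALSE)
  expect_equal(f1[18:30, 18:30], f2[23:35, 21:33], tolerance = 1e-10)
})

test_that("internal energy matches hand-computed finite differences", {
  pts <- rbind(c(0, 0), c(1, 0), c(2, 1))
  ctr <- snake_contour(pts, closed = FALSE)
  p <- snake_params(alpha = 1, beta = 1, continuity = "raw")
  e <- internal_energy(ctr, 2, p)
  expect_equal(e[["e_cont"]], 1)        # |v2 - v1|^2 = 1
  expect_equal(e[["e_curv"]], 1)        # |v1 - 2 v2 + v3|^2 = |(0,1)|^2
  # open-contour first point has no predecessor terms
  expect_equal(unname(internal_energy(ctr, 1, p)), c(0, 0))
  # zero weights kill both terms
  p0 <- snake_params(alpha = 0, beta = 0)
  expect_equal(unname(internal_energy(ctr, 2, p0)), c(0, 0))
  # equally spaced collinear points have zero curvature
  line <- snake_contour(cbind(1:5, 2), closed = FALSE)
  expect_equal(internal_energy(line, 3, p)[["e_curv"]], 0)
  expect_error(internal_energy(ctr, 9, p), "out of range")
})

test_that("a contour on a flat field with zero weights is a fixed point", {
  img <- matrix(0.5, 60, 60)
  init <- circle_contour(60, radius = 15, npts = 40)
  spacing <- 2 * pi * 15 / 40
  p <- snake_params(alpha = 0, beta = 0, resample_spacing = spacing)
  out <- evolve_snake(init, img, p)
  expect_equal(out$points, init$points, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(unlist(out$energy_trace) == 0))
})

test_that("snake energy trace is non-increasing within every scale level", {
  img <- disc_image()
  out <- evolve_snake(circle_contour(radius = 26), img, snake_params())
  for (tr in out$energy_trace) expect_true(all(diff(tr) <= 1e-9))
})

test_that("the snake converges onto a disc edge from outside", {
  img <- disc_image(radius = 20)
  out <- evolve_snake(circle_contour(radius = 30), img, snake_params())
  ctr <- (101 + 1) / 2
  rad <- sqrt((out$points[, 1] - ctr)^2 + (out$points[, 2] - ctr)^2)
  expect_lt(abs(mean(rad) - 20), 1)
})

test_that("vessel contour initialization respects margin and locality", {
  mask <- matrix(0, 40, 60)
  mask[18:23, 10:50] <- 1          # tube rows 18..23
  mask[32:35, 10:50] <- 1          # disjoint second vessel
  branch <- list(points = cbind(rep(20, 41), 10:50))

  ctr0 <- initialize_vessel_contour(mask, branch, margin = 0)
  expect_true(all(ctr0$points[, 1] >= 16.5 & ctr0$points[, 1] <= 24.5))

  ctr2 <- initialize_vessel_contour(mask, branch, margin = 2)
  expect_true(all(ctr2$points[, 1] >= 14.5 & ctr2$points[, 1] <= 26.5))
  # the disjoint vessel is not enclosed
  expect_true(all(ctr2$points[, 1] < 30))
  expect_true(ctr2$closed)
  expect_gte(nrow(ctr2$points), 3)

  expect_error(initialize_vessel_contour(mask, cbind(5, 5)), "foreground")
})

test_that("evolve_snake validates its inputs", {
  img <- matrix(0.5, 20, 20)
  outside <- snake_contour(rbind(c(-5, 1), c(5, 5), c(10, 10)))
  expect_error(evolve_snake(outside, img), "outside the image")
  expect_error(snake_contour(rbind(c(1, 1), c(2, 2))), "at least 3")
})
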