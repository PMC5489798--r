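# Image loading, thresholding and thinning.

test_that("single-channel images pass through load_image unchanged", {
  m <- matrix(round(seq(0, 255, length.out = 64)) / 255, 8, 8)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, f)
  expect_equal(load_image(f), m, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("channel policies select and combine planes correctly", {
  arr <- array(0, c(16, 16, 3))
  withr::with_seed(42, {
    arr[, , 1] <- matrix(sample(0:255, 256, TRUE) / 255, 16)
    arr[, , 3] <- matrix(sample(0:255, 256, TRUE) / 255, 16)
  })
  arr[, , 2] <- 7 / 255
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, f)

  expect_equal(load_image(f, "green"), matrix(7 / 255, 16, 16),
               tolerance = 1e-6, ignore_attr = TRUE)
  # per-pixel weighted-sum oracle, computed here from the raw planes
  lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  expect_equal(load_image(f, "luminance"), lum, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("load_image reads TIFF and plain PPM and rejects bad paths", {
  m <- matrix(runif(48), 6, 8)
  ft <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, ft, bits.per.sample = 16L)
  expect_equal(load_image(ft), m, tolerance = 1e-4, ignore_attr = TRUE)

  # ASCII PGM written by hand; values 0..255 row by row
  fp <- withr::local_tempfile(fileext = ".pgm")
  vals <- matrix(c(0, 64, 128, 255, 32, 16), 2, 3, byrow = TRUE)
  writeLines(c("P2", "3 2", "255",
               paste(t(vals), collapse = " ")), fp)
  expect_equal(load_image(fp), vals / 255, tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(load_image(tempfile(fileext = ".png")), "not found")
  fbad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", fbad)
  expect_error(load_image(fbad), "cannot read image")
})

test_that("binarize implements the strict threshold rule", {
  expect_equal(binarize(matrix(0, 3, 3), 0), matrix(0, 3, 3))
  # foreground iff intensity strictly exceeds S; ties go to background
  img <- matrix(c(200, 100, 128, 130), 2, 2)
  expect_equal(binarize(img, 128),
               matrix(c(1, 0, 0, 1), 2, 2))
  # dark-vessel polarity inverts the comparison
  expect_equal(binarize(img, 128, polarity = "dark_vessels"),
               matrix(c(0, 1, 0, 0), 2, 2))
})

test_that("binarize matches a per-pixel comparison oracle and is idempotent", {
  withr::with_seed(7, {
    img <- matrix(runif(64), 8, 8)
  })
  for (S in c(0.2, 0.5, 0.8)) {
    got <- binarize(img, S)
    expect_equal(got, (img > S) * 1)
    # idempotent on its own output: for the 0/1 image any threshold in
    # (0, 1) reproduces it
    expect_equal(binarize(got, 0.5), got)
  }
  expect_error(binarize(img, 2), "outside")
})

test_that("auto threshold separates a bimodal phantom", {
  ph <- generate_phantom(phantom_spec("straight", width_px = 8))
  mask <- binarize(ph$image, "auto")
  # recovered mask agrees with the analytic mask away from the 1-px
  # anti-aliased edge band
  expect_lt(abs(sum(mask) - sum(ph$truth$mask)) / sum(ph$truth$mask), 0.1)
})

test_that("skeletonize handles degenerate inputs", {
  empty <- matrix(0, 5, 5)
  expect_equal(skeletonize(empty), empty)
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(skeletonize(single), single)
})

test_that("a filled rectangle thins to a single one-pixel path", {
  m <- matrix(0, 9, 28); m[3:7, 4:25] <- 1
  sk <- skeletonize(m)
  expect_true(all(sk <= m))                       # subset of foreground
  expect_equal(count_components8(sk), 1L)
  # 1-px wide: no fully-foreground 2x2 block
  blocks <- sk[-nrow(sk), -ncol(sk)] + sk[-1, -ncol(sk)] +
            sk[-nrow(sk), -1] + sk[-1, -1]
  expect_true(all(blocks < 4))
  # a path spanning the rectangle: exactly 2 endpoints, rest inner
  pts <- detect_points(sk)
  expect_equal(nrow(pts$endpoints), 2L)
  expect_equal(nrow(pts$bifurcations), 0L)
  expect_gt(diff(range(which(sk == 1, arr.ind = TRUE)[, 2])), 15)
})

test_that("skeletonize is idempotent", {
  for (seed in 1:3) {
    m <- random_blob_mask(seed)
    sk <- skeletonize(m)
    expect_equal(skeletonize(sk), sk)
  }
})
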