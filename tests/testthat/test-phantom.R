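# Synthetic phantom generator and its ground truth.

test_that("phantom generation is deterministic under a fixed seed", {
  s <- phantom_spec("straight", width_px = 6, noise_sd = 0.05, seed = 13)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$mask, b$truth$mask)
  s2 <- phantom_spec("straight", width_px = 6, noise_sd = 0.05, seed = 14)
  expect_false(identical(generate_phantom(s2)$image, a$image))
})

test_that("a horizontal tube's mask has exact row thickness", {
  ph <- generate_phantom(phantom_spec("straight", width_px = 8,
                                      orientation_deg = 0))
  mask <- ph$truth$mask
  thickness <- colSums(mask)
  interior <- thickness[thickness > 0]
  # away from the rounded end caps the band is exactly 8 rows thick
  expect_true(all(interior[5:(length(interior) - 5)] == 8))
  # centerline lies inside the mask
  cl <- round(ph$truth$centerline)
  expect_true(all(mask[cl] == 1))
})

test_that("mask area matches the analytic width x length within 5%", {
  for (w in c(3, 8, 12)) {
    ph <- generate_phantom(phantom_spec("straight", width_px = w,
                                        orientation_deg = 30))
    cl <- ph$truth$centerline
    len <- sum(sqrt(rowSums(diff(cl)^2)))
    expect_lt(abs(sum(ph$truth$mask) - w * len) / (w * len), 0.05)
  }
})

test_that("degenerate contrast keeps the truth but flattens the image", {
  ph <- generate_phantom(phantom_spec("straight", width_px = 5,
                                      vessel_intensity = 0.3,
                                      background_intensity = 0.3))
  expect_equal(diff(range(ph$image)), 0)
  expect_gt(sum(ph$truth$mask), 0)
})

test_that("tapering width profile decreases along the tube", {
  ph <- generate_phantom(phantom_spec("tapering", width_px = c(12, 4)))
  expect_equal(ph$truth$width_at[1], 12)
  expect_equal(ph$truth$width_at[length(ph$truth$width_at)], 4)
  expect_true(all(diff(ph$truth$width_at) <= 0))
})

test_that("phantom parameter contracts are enforced", {
  expect_error(phantom_spec("straight", width_px = 0), ">= 1")
  expect_error(phantom_spec("tapering", width_px = 5), "start, end")
  expect_error(phantom_spec("bifurcation", width_px = c(5, 5)), "three arm")
  expect_error(generate_phantom(phantom_spec("straight", width_px = 200,
                                             image_size = c(60L, 60L))),
               "fit|bounds")
  expect_error(generate_bifurcation_phantom(
    phantom_spec("bifurcation", width_px = c(5, 5, 5)), arm_length = 0),
    "zero-length")
})

test_that("bifurcation phantom carries junction and arm truth", {
  ph <- generate_bifurcation_phantom(
    phantom_spec("bifurcation", width_px = c(5, 6, 7)))
  expect_length(ph$truth$arms, 3L)
  expect_equal(ph$truth$junction, c(80.5, 80.5))
  # all three arm centerlines start at the junction
  for (arm in ph$truth$arms)
    expect_equal(arm$centerline[1, ], ph$truth$junction,
                 ignore_attr = TRUE)
})

test_that("binary rendering has hard edges, anti-aliased rendering not", {
  sp_aa <- phantom_spec("straight", width_px = 7)
  sp_bin <- phantom_spec("straight", width_px = 7, antialias = FALSE)
  img_aa <- generate_phantom(sp_aa)$image
  img_bin <- generate_phantom(sp_bin)$image
  expect_equal(sort(unique(as.numeric(img_bin))), c(0.15, 0.85))
  expect_gt(length(unique(as.numeric(img_aa))), 2)
})
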