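# Skeleton pixel classification and branch tracing.

# Y-shaped skeleton: three straight arms meeting at (7, 7).
y_skeleton <- function() {
  sk <- matrix(0, 13, 13)
  sk[7, 7] <- 1
  for (k in 1:6) {
    sk[7 - k, 7] <- 1        # arm up
    sk[7 + k, 7 - k] <- 1    # arm down-left
    sk[7 + k, 7 + k] <- 1    # arm down-right
  }
  sk
}

test_that("classify_pixel follows the 3x3 neighbor-count rule", {
  sk <- matrix(0, 5, 5)
  sk[3, 3] <- 1
  expect_equal(classify_pixel(sk, c(3, 3)), "isolated")
  sk[3, 4] <- 1
  expect_equal(classify_pixel(sk, c(3, 3)), "endpoint")
  sk[3, 2] <- 1
  expect_equal(classify_pixel(sk, c(3, 3)), "inner")
  sk[2, 3] <- 1
  expect_equal(classify_pixel(sk, c(3, 3)), "bifurcation")
  expect_error(classify_pixel(sk, c(1, 1)), "foreground")
})

test_that("detect_points partitions a straight line and a Y correctly", {
  line <- matrix(0, 5, 14); line[3, 3:12] <- 1
  pts <- detect_points(line)
  expect_equal(nrow(pts$endpoints), 2L)
  expect_equal(nrow(pts$inner), 8L)
  expect_equal(nrow(pts$bifurcations), 0L)

  pts_y <- detect_points(y_skeleton())
  expect_equal(nrow(pts_y$endpoints), 3L)
  expect_equal(nrow(pts_y$bifurcations), 1L)
  expect_equal(pts_y$bifurcations[1, ], c(row = 7, col = 7))

  empty <- detect_points(matrix(0, 4, 4))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("the four point classes exactly cover the foreground", {
  for (seed in 1:5) {
    sk <- skeletonize(random_blob_mask(seed))
    pts <- detect_points(sk)
    expect_equal(sum(vapply(pts, nrow, integer(1))), sum(sk))
    all_pts <- do.call(rbind, pts)
    expect_equal(nrow(unique(all_pts)), nrow(all_pts))
  }
})

test_that("trace_branches recovers line, Y and disjoint topologies", {
  line <- matrix(0, 5, 14); line[3, 3:12] <- 1
  br <- trace_branches(line)
  expect_length(br, 1L)
  expect_equal(nrow(br[[1]]$points), 10L)
  expect_equal(br[[1]]$start_kind, "endpoint")
  expect_equal(br[[1]]$end_kind, "endpoint")
  # consecutive points 8-adjacent
  d <- diff(br[[1]]$points)
  expect_true(all(abs(d) <= 1) && all(rowSums(abs(d)) >= 1))

  br_y <- trace_branches(y_skeleton())
  expect_length(br_y, 3L)
  kinds <- vapply(br_y, function(b) sort(c(b$start_kind, b$end_kind))[1],
                  character(1))
  expect_true(all(kinds == "bifurcation"))
  expect_true(all(vapply(br_y, function(b) nrow(b$points), numeric(1)) == 7))

  two <- matrix(0, 9, 14); two[2, 3:12] <- 1; two[7, 3:12] <- 1
  expect_length(trace_branches(two), 2L)
})

test_that("every inner pixel lies on exactly one branch", {
  sk <- y_skeleton()
  br <- trace_branches(sk)
  interior <- do.call(rbind, lapply(br, function(b)
    b$points[-c(1, nrow(b$points)), , drop = FALSE]))
  pts <- detect_points(sk)
  expect_equal(nrow(unique(interior)), nrow(pts$inner))
})

test_that("a pure cycle is emitted as a closed branch with a warning", {
  # diamond ring: every pixel has exactly two 8-neighbors, no terminals
  sk <- matrix(0, 11, 11)
  for (r in 1:11) for (cc in 1:11)
    if (abs(r - 6) + abs(cc - 6) == 4) sk[r, cc] <- 1
  expect_warning(br <- trace_branches(sk), "loop")
  expect_length(br, 1L)
  expect_true(br[[1]]$closed)
  expect_equal(nrow(br[[1]]$points), sum(sk) + 1L)  # returns to its start
})
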