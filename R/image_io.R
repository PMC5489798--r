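#' Load an image as a grayscale matrix
#'
#' Reads PNG, TIFF, JPEG or PPM/PGM files and reduces them to a single
#' grayscale plane in `[0, 1]`. Fundus photographs are conventionally read
#' through the green channel, where the contrast between blood vessels and
#' background is highest; hand-labeled vessel maps are effectively
#' single-channel and pass through unchanged.
#'
#' @param path Path to a PNG/TIFF/JPEG/PPM/PGM image.
#' @param channel_policy How to reduce a 3-channel image: `"green"`
#'   (default), `"red"`, `"blue"`, or `"luminance"` (Rec. 601 weights
#'   0.299 R + 0.587 G + 0.114 B).
#' @return A numeric matrix `[row, col]` with values in `[0, 1]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- load_image(f)
#' dim(img)
#' @export
load_image <- function(path,
                       channel_policy = c("green", "luminance", "red", "blue")) {
  channel_policy <- match.arg(channel_policy)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)

  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("ppm", "pgm", "pbm")) {
    read_pnm_array(path)
  } else {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e)
                      stop("cannot read image '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    # EBImage stores images as [x, y(, channel)] = [col, row]; transpose to
    # the package's [row, col] convention.
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }

  gray <- if (length(dim(arr)) == 2L) {
    arr
  } else if (dim(arr)[3L] >= 3L) {
    switch(channel_policy,
           red       = arr[, , 1L],
           green     = arr[, , 2L],
           blue      = arr[, , 3L],
           luminance = 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] +
                       0.114 * arr[, , 3L])
  } else if (dim(arr)[3L] == 1L) {
    arr[, , 1L]
  } else {
    stop("unsupported channel count (", dim(arr)[3L], ") in '", path, "'",
         call. = FALSE)
  }
  gray <- pmin(pmax(gray, 0), 1)
  assert_gray(gray)
  gray
}

# PPM/PGM via pixmap; returned as [row, col(, channel)] in [0, 1].
read_pnm_array <- function(path) {
  pm <- tryCatch(pixmap::read.pnm(path),
                 error = function(e)
                   stop("cannot read image '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (methods::is(pm, "pixmapRGB")) {
    arr <- array(0, c(nrow(pm@red), ncol(pm@red), 3L))
    arr[, , 1L] <- pm@red; arr[, , 2L] <- pm@green; arr[, , 3L] <- pm@blue
    arr
  } else {
    pm@grey
  }
}

#' Binarize a grayscale image by thresholding
#'
#' Classic threshold segmentation: with polarity `"bright_vessels"` a pixel
#' becomes foreground (1) exactly when its intensity exceeds the threshold
#' `S`, and background (0) otherwise; `"dark_vessels"` inverts the
#' comparison for raw fundus photographs, where vessels are darker than the
#' fundus. Pixels exactly equal to `S` map to background in both polarities
#' (the strict inequalities leave the tie unassigned; background is the
#' documented choice).
#'
#' @param image Grayscale matrix (any finite numeric range).
#' @param threshold Scalar threshold `S`, or `"auto"` to select it by Otsu's
#'   criterion on the image histogram.
#' @param polarity `"bright_vessels"` (default; foreground above `S`) or
#'   `"dark_vessels"` (foreground below `S`).
#' @return A 0/1 matrix of the same shape.
#' @examples
#' img <- matrix(c(0.1, 0.9, 0.5, 0.2), 2, 2)
#' binarize(img, 0.5)
#' @export
binarize <- function(image, threshold = "auto",
                     polarity = c("bright_vessels", "dark_vessels")) {
  assert_gray(image)
  polarity <- match.arg(polarity)
  if (identical(threshold, "auto")) {
    threshold <- auto_threshold(image)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        !is.finite(threshold))
      stop("`threshold` must be a finite scalar or \"auto\"", call. = FALSE)
    rng <- range(image)
    if (threshold < rng[1L] || threshold > rng[2L])
      stop(sprintf("threshold %g outside image intensity range [%g, %g]",
                   threshold, rng[1L], rng[2L]), call. = FALSE)
  }
  out <- if (polarity == "bright_vessels") (image > threshold)
         else (image < threshold)
  mode(out) <- "numeric"
  out
}

# Otsu threshold; EBImage::otsu expects intensities in [0, 1], so rescale
# and map the threshold back to the original intensity units.
auto_threshold <- function(image) {
  rng <- range(image)
  if (rng[1L] == rng[2L]) return(rng[1L])
  scaled <- (image - rng[1L]) / (rng[2L] - rng[1L])
  s <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
  rng[1L] + s * (rng[2L] - rng[1L])
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen two-subiteration parallel thinning: each pass erodes the outer
#' pixel layer of the foreground while preserving 8-connectivity, and the
#' iteration stops when no more layers can be removed. The result is a
#' subset of the foreground, contains no fully-foreground 2x2 block, and
#' keeps the number of 8-connected components.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix of the same shape, the skeleton.
#' @examples
#' m <- matrix(0, 9, 24); m[3:7, 3:22] <- 1
#' sum(skeletonize(m)) < sum(m)
#' @export
skeletonize <- function(mask) {
  assert_binary(mask)
  if (!any(mask == 1)) return(mask)
  img <- mask

  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # 8 neighbors, Zhang-Suen numbering: p2=N, p3=NE, p4=E, p5=SE,
      # p6=S, p7=SW, p8=W, p9=NW (rows increase downward).
      p2 <- shift_mat(img, -1,  0); p3 <- shift_mat(img, -1,  1)
      p4 <- shift_mat(img,  0,  1); p5 <- shift_mat(img,  1,  1)
      p6 <- shift_mat(img,  1,  0); p7 <- shift_mat(img,  1, -1)
      p8 <- shift_mat(img,  0, -1); p9 <- shift_mat(img, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- img == 1 & B >= 2 & B <= 6 & A == 1
      cond <- cond & if (step == 1) {
        (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        # Parallel deletion can erase a small component entirely (an
        # isolated 2x2 block matches both templates at every pixel).
        # Guard: any component all of whose pixels are deleted this
        # subiteration is re-seeded with its top-left pixel, preserving
        # the 8-connected component count.
        img2 <- img
        img2[cond] <- 0
        lab <- label_components8(img)
        surviving <- unique(lab[img2 == 1])
        vanished <- setdiff(unique(lab[lab > 0]), surviving)
        for (v in vanished) {
          px <- which(lab == v, arr.ind = TRUE)
          px <- px[order(px[, 1L], px[, 2L])[1L], ]
          img2[px[1L], px[2L]] <- 1
        }
        if (!identical(img2, img)) changed <- TRUE
        img <- img2
      }
    }
    if (!changed) break
  }
  prune_redundant(img)
}

# 8-connected component labeling (BFS flood fill), 0 = background.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  fg <- which(mask == 1)
  for (start in fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + rr
        if (mask[q] == 1 && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Post-thinning cleanup: parallel two-subiteration thinning leaves
# two-pixel staircases on diagonal runs, which the 3x3 classifier would
# read as spurious bifurcations. Sequentially delete any non-endpoint
# pixel whose foreground 8-neighbors remain a single connected set without
# it (a simple point), reducing staircases to minimal 8-connected digital
# curves while preserving endpoints and component count.
prune_redundant <- function(img) {
  # ring positions: N, NE, E, SE, S, SW, W, NW
  roff <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  coff <- c(0, 1, 1, 1, 0, -1, -1, -1)
  # adjacency between ring cells: consecutive, plus cardinal pairs two
  # apart (N-E, E-S, S-W, W-N are diagonally adjacent cells)
  adj <- matrix(FALSE, 8, 8)
  for (i in 1:8) {
    j <- i %% 8 + 1
    adj[i, j] <- adj[j, i] <- TRUE
  }
  for (i in c(1, 3, 5, 7)) {
    j <- (i + 1) %% 8 + 1
    adj[i, j] <- adj[j, i] <- TRUE
  }
  nr <- nrow(img); nc <- ncol(img)
  repeat {
    fg <- which(img == 1, arr.ind = TRUE)
    fg <- fg[order(fg[, 1L], fg[, 2L]), , drop = FALSE]
    deleted <- FALSE
    for (k in seq_len(nrow(fg))) {
      r <- fg[k, 1L]; cc <- fg[k, 2L]
      if (img[r, cc] != 1) next
      rr <- r + roff; ccn <- cc + coff
      ok <- rr >= 1 & rr <= nr & ccn >= 1 & ccn <= nc
      on <- logical(8)
      on[ok] <- img[cbind(rr[ok], ccn[ok])] == 1
      deg <- sum(on)
      if (deg < 2L) next
      # count connected components of the active ring cells
      idx <- which(on)
      comp <- seq_along(idx)
      repeat {
        merged <- FALSE
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
          if (comp[a] != comp[b] && adj[idx[a], idx[b]]) {
            comp[comp == comp[b]] <- comp[a]
            merged <- TRUE
          }
        }
        if (!merged) break
      }
      if (length(unique(comp)) == 1L) {
        img[r, cc] <- 0
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  img
}

# Shift a matrix by (dr, dc), zero-filling exposed cells.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Write a binary or grayscale matrix as a PNG image
#'
#' @param image Matrix in `[0, 1]` (binary masks are written as 0/255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  assert_gray(image)
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(image, 0), 1))), path,
                      type = "png")
  invisible(path)
}
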