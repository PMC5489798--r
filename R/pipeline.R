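# End-to-end measurement pipeline and configuration.

#' Pipeline configuration
#'
#' All stage parameters of the measurement chain with documented defaults.
#' The configuration serializes to YAML (see [write_config()] /
#' [read_config()]) and round-trips unchanged.
#'
#' @param threshold Binarization threshold, a number or `"auto"` (Otsu).
#' @param polarity `"bright_vessels"` (hand-labeled maps) or
#'   `"dark_vessels"` (raw fundus photographs).
#' @param channel Channel policy for color images (see [load_image()]).
#' @param epsilon Douglas-Peucker tolerance, pixels.
#' @param snake A [snake_params()] list.
#' @param snake_on `"image"` evolves the snake on the grayscale
#'   intensities; `"mask"` on the binary segmentation.
#' @param margin Outward offset of the initial contour, pixels.
#' @param min_branch_length Centerline branches shorter than this many
#'   pixels are not measured.
#' @param junction_trim Pixels trimmed from bifurcation-terminated branch
#'   ends before measurement (see [trim_junction_pixels()]).
#' @param seed Seed for any stochastic stage (kept for reproducibility
#'   metadata; the default pipeline is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = "auto",
                            polarity = c("bright_vessels", "dark_vessels"),
                            channel = c("green", "luminance", "red", "blue"),
                            epsilon = 1.0,
                            snake = snake_params(),
                            snake_on = c("image", "mask"),
                            margin = 2,
                            min_branch_length = 10L,
                            junction_trim = 5L,
                            seed = 1L) {
  polarity <- match.arg(polarity)
  channel <- match.arg(channel)
  snake_on <- match.arg(snake_on)
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || length(threshold) != 1L))
    stop("config field `threshold` must be a number or \"auto\"",
         call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("config field `epsilon` must be positive", call. = FALSE)
  if (!inherits(snake, "snake_params"))
    stop("config field `snake` must be a snake_params object", call. = FALSE)
  if (!is.numeric(margin) || margin < 0)
    stop("config field `margin` must be >= 0", call. = FALSE)
  if (!is.numeric(min_branch_length) || min_branch_length < 2)
    stop("config field `min_branch_length` must be >= 2", call. = FALSE)
  if (!is.numeric(junction_trim) || junction_trim < 0)
    stop("config field `junction_trim` must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, polarity = polarity,
                 channel = channel, epsilon = epsilon, snake = snake,
                 snake_on = snake_on, margin = margin,
                 min_branch_length = as.integer(min_branch_length),
                 junction_trim = as.integer(junction_trim),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$snake <- unclass(lst$snake)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::yaml.load_file(path)
  snake <- do.call(snake_params, lst$snake[
    setdiff(names(lst$snake), character(0))])
  lst$snake <- snake
  do.call(pipeline_config, lst)
}

#' Run the full vessel-diameter measurement pipeline
#'
#' Executes binarization, thinning, skeleton-point detection, branch
#' tracing, Douglas-Peucker characteristic-point extraction, snake contour
#' detection and Heron's-formula diametry on one image, and optionally
#' writes the CSV/JSON/PNG artifacts.
#'
#' @param image A file path (PNG/TIFF/JPEG/PPM) or a grayscale matrix.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts (`points.csv`,
#'   `characteristic_points.csv`, `contours.csv`, `diameters.csv`,
#'   `report.json`, overlay PNG).
#' @param verbose Print stage-level progress.
#' @return A list with `diameters` (data frame: `branch_id`, `segment_id`,
#'   chord coordinates, `h1`, `h2`, `diameter`), `points` (detected
#'   skeleton point classes), `branches`, `characteristic_points`,
#'   `contours`, `compression` (overall `N_total`, `n_kept`, `dcr`), and
#'   `n_vessels`. An image with no vessels yields empty tables, not an
#'   error.
#' @examples
#' ph <- generate_phantom(phantom_spec("straight", width_px = 8))
#' res <- run_pipeline(ph$image)
#' mean(res$diameters$diameter)
#' @export
run_pipeline <- function(image, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  gray <- if (is.character(image)) load_image(image, config$channel)
          else assert_gray(image)

  mask <- binarize(gray, config$threshold, config$polarity)
  skel <- skeletonize(mask)
  pts <- detect_points(skel)
  say("skeleton: %d endpoints, %d bifurcations, %d inner points",
      nrow(pts$endpoints), nrow(pts$bifurcations), nrow(pts$inner))

  branches <- trace_branches(skel, min_length = config$min_branch_length)
  say("traced %d branches", length(branches))

  snake_image <- if (config$snake_on == "mask") mask else gray
  diam_rows <- list()
  cp_rows <- list()
  contour_rows <- list()
  N_total <- 0L; n_kept <- 0L

  for (b in seq_along(branches)) {
    br <- branches[[b]]
    if (br$closed) next
    br_meas <- trim_junction_pixels(br, config$junction_trim)
    cp <- douglas_peucker(br_meas$points, config$epsilon)
    N_total <- N_total + nrow(br_meas$points)
    n_kept <- n_kept + nrow(cp)
    contour <- tryCatch(
      initialize_vessel_contour(mask, br, margin = config$margin),
      error = function(e) NULL)
    if (is.null(contour)) next
    snk <- evolve_snake(contour, snake_image, config$snake)
    say("branch %d: %d centerline px -> %d characteristic pts, %d contour pts, %d sweeps",
        b, nrow(br$points), nrow(cp), nrow(snk$points), snk$sweeps)
    meas <- suppressWarnings(measure_vessel(cp, snk))
    meas <- cbind(branch_id = b, meas)
    diam_rows[[length(diam_rows) + 1L]] <- meas
    cp_rows[[length(cp_rows) + 1L]] <-
      data.frame(branch_id = b, row = cp[, 1L], col = cp[, 2L])
    contour_rows[[length(contour_rows) + 1L]] <-
      data.frame(branch_id = b, row = snk$points[, 1L],
                 col = snk$points[, 2L])
  }

  empty_diam <- data.frame(branch_id = integer(), segment_id = integer(),
                           row_N = numeric(), col_N = numeric(),
                           row_P = numeric(), col_P = numeric(),
                           h1 = numeric(), h2 = numeric(),
                           diameter = numeric())
  diameters <- if (length(diam_rows)) do.call(rbind, diam_rows) else empty_diam
  result <- list(
    diameters = diameters,
    points = pts,
    branches = branches,
    characteristic_points = if (length(cp_rows)) do.call(rbind, cp_rows)
      else data.frame(branch_id = integer(), row = numeric(),
                      col = numeric()),
    contours = if (length(contour_rows)) do.call(rbind, contour_rows)
      else data.frame(branch_id = integer(), row = numeric(),
                      col = numeric()),
    compression = list(
      N_total = N_total, n_kept = n_kept,
      dcr = if (N_total > 0) compression_ratio(N_total, n_kept) else NA_real_),
    n_vessels = length(branches))
  if (result$n_vessels == 0L) say("no vessels found")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, mask, skel, out_dir)
  result
}

write_pipeline_artifacts <- function(result, mask, skel, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_points_csv(result$points, file.path(out_dir, "points.csv"))
  utils::write.csv(result$characteristic_points,
                   file.path(out_dir, "characteristic_points.csv"),
                   row.names = FALSE)
  utils::write.csv(result$contours, file.path(out_dir, "contours.csv"),
                   row.names = FALSE)
  utils::write.csv(result$diameters, file.path(out_dir, "diameters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_vessels = result$n_vessels,
         n_measurements = sum(!is.na(result$diameters$diameter)),
         mean_diameter_px = mean(result$diameters$diameter, na.rm = TRUE),
         compression = result$compression),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write_image_png(mask, file.path(out_dir, "mask.png"))
  write_image_png(skel, file.path(out_dir, "skeleton.png"))
  overlay <- overlay_rgb(mask, result)
  EBImage::writeImage(overlay, file.path(out_dir, "overlay.png"),
                      type = "png")
  invisible(out_dir)
}

# RGB overlay: mask in gray, contours green, characteristic points red,
# endpoints blue, bifurcations yellow.
overlay_rgb <- function(mask, result) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- g <- b <- 0.5 * mask
  paint <- function(pts, col) {
    if (is.null(pts) || nrow(pts) == 0L) return()
    pr <- pmin(pmax(round(pts[, 1L]), 1), nr)
    pc <- pmin(pmax(round(pts[, 2L]), 1), nc)
    idx <- cbind(pr, pc)
    r[idx] <<- col[1L]; g[idx] <<- col[2L]; b[idx] <<- col[3L]
  }
  if (nrow(result$contours)) paint(as.matrix(result$contours[, c("row", "col")]), c(0, 1, 0))
  if (nrow(result$characteristic_points))
    paint(as.matrix(result$characteristic_points[, c("row", "col")]),
          c(1, 0, 0))
  paint(result$points$endpoints, c(0, 0.4, 1))
  paint(result$points$bifurcations, c(1, 1, 0))
  arr <- array(0, c(nc, nr, 3))   # EBImage expects [x, y, channel]
  arr[, , 1] <- t(r); arr[, , 2] <- t(g); arr[, , 3] <- t(b)
  EBImage::Image(arr, colormode = "Color")
}

#' Evaluate paired manual-versus-method diameters from a CSV
#'
#' Reads a CSV with columns `image`, `vessel`, `manual`, `proposed` and
#' computes, per image, the signed differences, the mean absolute
#' difference E_avg, and both dispersion measures (see
#' [sd_printed_formula()]).
#'
#' @param pairs A CSV path or a data frame with those columns.
#' @param out_csv Optional path for the per-image statistics CSV.
#' @return A list with `per_vessel` (input plus `difference`) and
#'   `per_image` (columns `image`, `n`, `sd_printed_formula`, `sd_sample`,
#'   `e_avg`).
#' @examples
#' tab <- reference_tables()$pairs
#' ev <- run_evaluation(tab)
#' ev$per_image
#' @export
run_evaluation <- function(pairs, out_csv = NULL) {
  df <- if (is.character(pairs)) {
    if (!file.exists(pairs)) stop("cannot read: ", pairs, call. = FALSE)
    utils::read.csv(pairs)
  } else as.data.frame(pairs)
  needed <- c("image", "vessel", "manual", "proposed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("evaluation input lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$manual) | !is.finite(df$proposed))
  if (length(bad))
    stop("non-numeric diameter at line ", bad[1L] + 1L, call. = FALSE)

  df$difference <- df$manual - df$proposed
  images <- unique(df$image)
  per_image <- do.call(rbind, lapply(images, function(im) {
    sub <- df[df$image == im, ]
    p <- paired_diameters(sub$manual, sub$proposed, image_id = im)
    s <- sd_printed_formula(p)
    data.frame(image = im, n = p$n,
               sd_printed_formula = s$sd_printed_formula,
               sd_sample = s$sd_sample, e_avg = e_avg(p))
  }))
  if (!is.null(out_csv))
    utils::write.csv(per_image, out_csv, row.names = FALSE)
  list(per_vessel = df, per_image = per_image)
}
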