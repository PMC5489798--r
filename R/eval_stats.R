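# Paired manual-versus-method evaluation statistics.
#
# For each image, n vessels are measured both by hand (x) and by the
# pipeline (xbar). The per-vessel signed difference is x - xbar, the mean
# absolute difference is E_avg = sum(|x - xbar|) / n, and the dispersion is
# reported two ways: the root-mean-square of the differences
# sqrt(sum(|x - xbar|^2) / n) (the form used by the source tables' text)
# and, as a diagnostic, the conventional sample standard deviation of the
# signed differences (divisor n - 1).

#' Bundle paired manual and method diameters
#'
#' @param manual,measured Equal-length positive numeric vectors of
#'   diameters in pixels (manual reference and method output).
#' @param image_id Optional label.
#' @return An object of class `paired_diameters`.
#' @export
paired_diameters <- function(manual, measured, image_id = NA_character_) {
  if (length(manual) != length(measured))
    stop("`manual` and `measured` must have equal length", call. = FALSE)
  if (length(manual) < 1L)
    stop("need at least one measurement pair", call. = FALSE)
  if (any(!is.finite(manual)) || any(!is.finite(measured)) ||
      any(manual <= 0) || any(measured <= 0))
    stop("diameters must be finite and positive", call. = FALSE)
  structure(list(image_id = image_id, manual = as.numeric(manual),
                 measured = as.numeric(measured), n = length(manual)),
            class = "paired_diameters")
}

#' Signed differences between manual and method diameters
#'
#' @param pairs A [paired_diameters()] object.
#' @return Numeric vector `manual - measured`, one element per vessel.
#' @examples
#' diameter_differences(paired_diameters(6.6212, 6.6436))  # -0.0224
#' @export
diameter_differences <- function(pairs) {
  stopifnot(inherits(pairs, "paired_diameters"))
  pairs$manual - pairs$measured
}

#' Mean absolute difference E_avg
#'
#' `E_avg = sum(|x - xbar|) / n` over the n measurement pairs.
#'
#' @param pairs A [paired_diameters()] object.
#' @return Non-negative scalar.
#' @export
e_avg <- function(pairs) {
  d <- diameter_differences(pairs)
  sum(abs(d)) / length(d)
}

#' Root-mean-square difference and sample standard deviation
#'
#' Evaluates `sqrt(sum(|x - xbar|^2) / n)` (the dispersion formula printed
#' alongside the reference tables) and, for comparison, the conventional
#' sample standard deviation of the signed differences (divisor `n - 1`,
#' `NA` for a single pair).
#'
#' @param pairs A [paired_diameters()] object.
#' @return List with `sd_printed_formula` and `sd_sample`.
#' @export
sd_printed_formula <- function(pairs) {
  d <- diameter_differences(pairs)
  list(sd_printed_formula = sqrt(sum(abs(d)^2) / length(d)),
       sd_sample = if (length(d) >= 2L) stats::sd(d) else NA_real_)
}

#' Evaluation statistics for one image
#'
#' @param pairs A [paired_diameters()] object.
#' @return List with `image_id`, `n`, `differences`, `e_avg`,
#'   `sd_printed_formula`, `sd_sample`.
#' @export
eval_stats <- function(pairs) {
  sds <- sd_printed_formula(pairs)
  list(image_id = pairs$image_id, n = pairs$n,
       differences = diameter_differences(pairs),
       e_avg = e_avg(pairs),
       sd_printed_formula = sds$sd_printed_formula,
       sd_sample = sds$sd_sample)
}

#' Published STARE/HRF diameter comparison fixture
#'
#' Returns the 30 paired (manual, proposed-method) vessel diameters for the
#' six STARE and HRF fundus images shipped with the package, together with
#' the published per-vessel differences and per-image statistics, as plain
#' data frames read from `inst/extdata`.
#'
#' @return List of two data frames: `pairs` (columns `dataset`, `image`,
#'   `vessel`, `manual`, `proposed`, `difference_printed`) and
#'   `image_stats` (columns `image`, `sd_printed`, `eavg_printed`).
#' @export
reference_tables <- function() {
  pairs <- utils::read.csv(system.file("extdata", "tables_1_2.csv",
                                       package = "vesselcaliper"),
                           colClasses = c(difference_printed = "character"))
  image_stats <- utils::read.csv(system.file("extdata",
                                             "tables_1_2_image_stats.csv",
                                             package = "vesselcaliper"))
  list(pairs = pairs, image_stats = image_stats)
}
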