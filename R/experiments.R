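#' MI-depth recovery experiment on in-memory phantoms
#'
#' Draws a cohort of phantom geometries with infiltration fractions sampled
#' uniformly from \code{f_range}, measures each case's MI depth on the
#' ground-truth masks, and returns the paired true/recovered values. This is
#' the package's core calibration check: the measured depth should track the
#' constructed fraction closely, and staging should agree away from the 0.5
#' boundary.
#'
#' @param n_cases number of phantoms.
#' @param f_range interval for the infiltration fraction.
#' @param seed master seed.
#' @param image_size slice size in pixels.
#' @param bend_range interval for the curvature coefficient.
#' @return data frame with true_mi, mi_depth, true_stage, pred_stage.
#' @export
mi_recovery_experiment <- function(n_cases = 200L, f_range = c(0.05, 0.95),
                                   seed = 1L, image_size = c(512L, 512L),
                                   bend_range = c(0, 0)) {
  set.seed(seed)
  w <- image_size[1L]; h <- image_size[2L]
  sc <- min(w, h) / 512
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    A <- stats::runif(1, 120, 170) * sc
    B <- stats::runif(1, 60 * sc, min(95 * sc, A - 20 * sc))
    spec <- phantom_spec(
      image_size = image_size,
      uterus_center = c(w / 2, h / 2) + stats::runif(2, -15, 15) * sc,
      semi_axes = c(A, B),
      orientation = stats::runif(1, -0.5, 0.5),
      bend = stats::runif(1, bend_range[1L], bend_range[2L]),
      tumor_arc = stats::runif(1, pi / 3, 2 * pi / 3) +
        c(-1, 1) * stats::runif(1, 0.25, 0.5),
      infiltration_fraction = stats::runif(1, f_range[1L], f_range[2L]),
      band_halfwidth = max(2 * sc, 1),
      seed = sample.int(.Machine$integer.max, 1L))
    case <- make_phantom(spec)
    mi <- measure_mi(case$mask, case$mask, generate_ucl(case$mask))
    rows[[i]] <- data.frame(true_mi = case$true_mi, mi_depth = mi$mi_depth,
                            true_stage = case$true_stage, pred_stage = mi$stage)
  }
  do.call(rbind, rows)
}
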