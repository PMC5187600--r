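# Experiment harness: noise-robustness and localization-radius protocols,
# Dice reporting, and CSV serialization.

report_columns <- c("phantom", "model", "radius", "m", "noise_variance",
                    "seed", "dice", "iterations", "final_energy", "converged")

new_report_row <- function(phantom, model, radius, m, noise_variance, seed,
                           result, truth) {
  data.frame(phantom = phantom, model = model, radius = radius, m = m,
             noise_variance = noise_variance, seed = seed,
             dice = dice_coefficient(result$binary_mask, truth),
             iterations = result$iterations_run,
             final_energy = result$energy_trace[length(result$energy_trace)],
             converged = result$converged,
             stringsAsFactors = FALSE)
}

#' Noise-robustness experiment
#'
#' For every (seed, variance) pair, generates the circle + rectangle phantom
#' at that noise level, runs both the localized model and the global FEAC
#' baseline from the phantom's default seed rectangles, and records the Dice
#' coefficient against the clean ground truth.
#'
#' @param seeds Integer vector of phantom noise seeds.
#' @param variances Noise variances on the \[0, 1\] scale (default the
#'   protocol levels 0.01, 0.10, 0.20).
#' @param params [model_params()] for the localized model (its `m`,
#'   `max_iterations`, and `band_width` are shared with the baseline).
#' @param size Phantom side length (default 128).
#' @return A data frame (the experiment report), one row per
#'   (seed, variance, model).
#' @export
run_noise_robustness <- function(seeds = 1:5,
                                 variances = c(0.01, 0.10, 0.20),
                                 params = model_params(),
                                 size = 128L) {
  rows <- list()
  fp <- feac_params(m = params$m, max_iterations = params$max_iterations,
                    band_width = params$band_width,
                    energy_tolerance = params$energy_tolerance)
  for (seed in seeds) {
    for (v in variances) {
      ph <- circle_rectangle_phantom(noise_variance = v, seed = seed,
                                     size = size)
      id <- sprintf("circle_rectangle_v%03d", round(100 * v))
      loc <- segment(ph$image, ph$init, params)
      fea <- feac_segment(ph$image, ph$init, fp)
      rows[[length(rows) + 1L]] <-
        new_report_row(id, "localized", params$radius, params$m, v, seed,
                       loc, ph$truth)
      rows[[length(rows) + 1L]] <-
        new_report_row(id, "feac", NA_integer_, params$m, v, seed,
                       fea, ph$truth)
    }
  }
  do.call(rbind, rows)
}

#' Localization-radius sensitivity experiment
#'
#' Runs the localized model on the intensity-inhomogeneous phantom at each
#' radius (default the protocol radii 10, 15, 20, 25, 30, at 200
#' iterations) and records the Dice coefficient per radius.  Too small a
#' radius is too local to find the boundary from the initialization; too
#' large a radius approaches the (failing) global model; intermediate radii
#' do best.
#'
#' @param radii Integer vector of localization radii.
#' @param params [model_params()]; its radius field is overridden per run.
#' @param seed Phantom seed.
#' @param size Phantom side length (default 128).
#' @return A data frame, one row per radius.
#' @export
run_radius_sweep <- function(radii = c(10L, 15L, 20L, 25L, 30L),
                             params = model_params(max_iterations = 200L),
                             seed = 1L, size = 128L) {
  ph <- inhomogeneous_phantom(seed = seed, size = size)
  rows <- lapply(radii, function(r) {
    p <- params
    p$radius <- as.integer(r)
    res <- segment(ph$image, ph$init, p)
    new_report_row("inhomogeneous", "localized", r, p$m, NA_real_, seed,
                   res, ph$truth)
  })
  do.call(rbind, rows)
}

#' Write / read an experiment report as CSV
#'
#' Fixed column order (`phantom, model, radius, m, noise_variance, seed,
#' dice, iterations, final_energy, converged`); numeric columns are written
#' at full double precision so the round trip is lossless.
#'
#' @param report Data frame from [run_noise_robustness()] or
#'   [run_radius_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly (for `save_report`); the data frame (for
#'   `read_report`).
#' @export
save_report <- function(report, path) {
  if (nrow(report) > 0L) {
    missing_cols <- setdiff(report_columns, names(report))
    if (length(missing_cols) > 0L)
      stop_validation("report is missing columns: ",
                      paste(missing_cols, collapse = ", "))
    report <- report[, report_columns]
    for (col in c("dice", "final_energy", "noise_variance", "m"))
      report[[col]] <- sprintf("%.17g", report[[col]])
  } else {
    report <- as.data.frame(
      setNames(replicate(length(report_columns), character(0),
                         simplify = FALSE), report_columns))
  }
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_report
#' @export
read_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(phantom = "character", model = "character",
                                radius = "integer", m = "numeric",
                                noise_variance = "numeric", seed = "integer",
                                dice = "numeric", iterations = "integer",
                                final_energy = "numeric",
                                converged = "logical"))
  df[, report_columns]
}

#' Best global threshold Dice (separability oracle)
#'
#' Exhaustively sweeps intensity thresholds and returns the best Dice
#' achievable by any single global threshold (in either polarity) against
#' the ground truth.  Used to certify that the inhomogeneous phantom is not
#' globally separable.
#'
#' @param image Intensity matrix.
#' @param truth Ground-truth logical mask.
#' @param n_thresholds Number of thresholds in the sweep (default 256).
#' @return Best achievable Dice coefficient.
#' @export
best_threshold_dice <- function(image, truth, n_thresholds = 256L) {
  ths <- seq(min(image), max(image), length.out = n_thresholds)
  best <- 0
  for (t in ths) {
    best <- max(best,
                dice_coefficient(image > t, truth),
                dice_coefficient(image <= t, truth))
  }
  best
}
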