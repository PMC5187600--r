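# Narrow-band sweep optimizer.
#
# Instead of a gradient flow, the contour is evolved by direct energy
# descent: each pixel in a narrow band around the current 0.5-level gets the
# closed-form optimal membership candidate; the exact energy change of that
# single-pixel move is computed in closed form, and the move is accepted iff
# it strictly decreases the total energy.  Patch statistics are updated
# immediately after every accepted move (Gauss-Seidel style), so the closed
# forms remain exact throughout a sweep.

#' Model parameters for the localized patch-based contour
#'
#' @param radius Localization radius r in pixels (disc patch; default 20).
#' @param m Fuzzifier exponent (> 1; default 2).
#' @param max_iterations Hard cap on narrow-band sweeps (default 200).
#' @param band_width Chebyshev half-width of the narrow band, in pixels
#'   (default 2; the band is rebuilt before every sweep).
#' @param energy_tolerance Relative convergence tolerance: the solver stops
#'   when the energy decrease of a full sweep is below
#'   `energy_tolerance * F_initial` (default 1e-10).
#' @param model `"localized"` (patch-local prototypes) or `"feac"` (global
#'   prototypes baseline).
#' @return A validated parameter list of class `model_params`.
#' @export
model_params <- function(radius = 20L, m = 2, max_iterations = 200L,
                         band_width = 2L, energy_tolerance = 1e-10,
                         model = c("localized", "feac")) {
  model <- match.arg(model)
  if (radius < 1 || radius != round(radius))
    stop_validation("radius must be an integer >= 1")
  assert_fuzzifier(m)
  if (band_width < 1 || band_width != round(band_width))
    stop_validation("band_width must be an integer >= 1")
  if (max_iterations < 0) stop_validation("max_iterations must be >= 0")
  structure(list(radius = as.integer(radius), m = m,
                 max_iterations = as.integer(max_iterations),
                 band_width = as.integer(band_width),
                 energy_tolerance = energy_tolerance, model = model),
            class = "model_params")
}

#' Narrow band around the current contour
#'
#' Returns the pixels whose Chebyshev distance to a pixel on the opposite
#' side of the 0.5 threshold is at most `band_width` — i.e. the full set of
#' 0.5-transitions plus a margin.  Only these pixels are visited by a sweep;
#' the band is rebuilt whenever the contour has moved.
#'
#' @param u Membership matrix.
#' @param band_width Chebyshev radius of the band (>= 1).
#' @return Object of class `narrow_band`: list with `pixels` (n x 2 integer
#'   matrix of (row, col), raster order: by row, then column) and
#'   `band_width`.  `pixels` has zero rows when u has no 0.5-transition.
#' @export
extract_narrow_band <- function(u, band_width = 2L) {
  assert_membership(u)
  if (band_width < 1) stop_validation("band_width must be >= 1")
  w <- as.integer(band_width)
  b <- u > 0.5
  nr <- nrow(b); nc <- ncol(b)
  band <- matrix(FALSE, nr, nc)
  for (dy in -w:w) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    in_y <- seq_len(nr) + dy >= 1L & seq_len(nr) + dy <= nr
    for (dx in -w:w) {
      if (dy == 0L && dx == 0L) next
      xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      in_x <- seq_len(nc) + dx >= 1L & seq_len(nc) + dx <= nc
      shifted <- b[ys, xs, drop = FALSE]
      valid <- outer(in_y, in_x, "&")
      band <- band | (valid & (shifted != b))
    }
  }
  pix <- which(band, arr.ind = TRUE)
  ord <- order(pix[, 1], pix[, 2])
  pixels <- matrix(as.integer(pix[ord, , drop = FALSE]), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  structure(list(pixels = pixels, band_width = w), class = "narrow_band")
}

#' @export
print.narrow_band <- function(x, ...) {
  cat("narrow band:", nrow(x$pixels), "pixels, width", x$band_width, "\n")
  invisible(x)
}

#' One full narrow-band sweep
#'
#' Visits the band pixels in raster order; for each, computes the membership
#' candidate from that pixel's own patch prototypes, the exact energy change
#' of adopting it, and accepts iff the change is strictly negative.  On
#' acceptance every affected patch center's statistics are updated in place
#' before the next pixel is visited.
#'
#' @param image Intensity matrix.
#' @param u Membership matrix.
#' @param stats Current local statistics (consistent with `u`).
#' @param band A [extract_narrow_band()] result.
#' @param params A [model_params()] list.
#' @param mask Optional precomputed [make_disc_mask()] (rebuilt from
#'   `params$radius` when omitted).
#' @return List with updated `u` and `stats`, `accepted` (count of adopted
#'   changes) and `delta_f` (their summed energy change, <= 0).
#' @export
sweep_iteration <- function(image, u, stats, band, params, mask = NULL) {
  if (is.null(mask)) mask <- make_disc_mask(params$radius)
  if (nrow(band$pixels) == 0L)
    return(list(u = u, stats = stats, accepted = 0L, delta_f = 0))
  res <- sweep_cpp(image, u + 0, stats$s1 + 0, stats$s2 + 0,
                   stats$c1 + 0, stats$c2 + 0,
                   band$pixels - 1L, mask$offsets, params$m)
  list(u = res$u,
       stats = structure(list(s1 = res$s1, s2 = res$s2,
                              c1 = res$c1, c2 = res$c2,
                              radius = mask$radius, m = params$m),
                         class = "local_statistics"),
       accepted = res$accepted, delta_f = res$delta_f)
}

#' Segment an image with the localized patch-based fuzzy contour
#'
#' Full pipeline: initial membership from the seed regions, dense local
#' statistics, then repeated narrow-band sweeps until no single-pixel change
#' decreases the energy, the energy decrease falls below the relative
#' tolerance, or `max_iterations` is reached.  The energy trace is
#' non-increasing by construction (only strictly energy-decreasing moves are
#' accepted).  Incrementally maintained statistics are resynchronized from
#' scratch every 50 sweeps to guard against floating-point drift.
#'
#' @param image Intensity matrix in \[0, 1\] (see [load_image()]).
#' @param seeds Seed regions as in [init_membership()], or an existing
#'   membership matrix.
#' @param params A [model_params()] list.  With `params$model == "feac"`
#'   the call is forwarded to [feac_segment()] with unit class weights.
#' @return Object of class `fuzzac_segmentation`: list with `membership`,
#'   `binary_mask` (membership > 0.5), `energy_trace` (F at iteration 0..n),
#'   `iterations_run`, `converged`, and the parameters used.
#' @export
segment <- function(image, seeds, params = model_params()) {
  assert_image(image)
  if (params$model == "feac")
    return(feac_segment(image, seeds,
                        feac_params(m = params$m,
                                    max_iterations = params$max_iterations,
                                    band_width = params$band_width,
                                    energy_tolerance = params$energy_tolerance)))
  u <- as_initial_membership(image, seeds)
  mask <- make_disc_mask(params$radius)
  stats <- compute_local_statistics(image, u, mask, params$m)
  f0 <- total_localized_energy(image, u, stats, mask, params$m)
  trace <- f0
  f <- f0
  tol <- params$energy_tolerance * max(f0, .Machine$double.xmin)
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    band <- extract_narrow_band(u, params$band_width)
    if (nrow(band$pixels) == 0L) {
      if (it == 0L) warning("initial membership has no 0.5-contour; ",
                            "returning the initial partition")
      converged <- TRUE
      break
    }
    sw <- sweep_iteration(image, u, stats, band, params, mask)
    it <- it + 1L
    u <- sw$u
    stats <- sw$stats
    f <- f + sw$delta_f
    trace <- c(trace, f)
    if (sw$accepted == 0L || abs(sw$delta_f) < tol) {
      converged <- TRUE
      break
    }
    if (it %% 50L == 0L)
      stats <- compute_local_statistics(image, u, mask, params$m)
  }
  new_segmentation(u, trace, it, converged, params)
}

as_initial_membership <- function(image, seeds) {
  if (is.matrix(seeds) && is.numeric(seeds) &&
      identical(dim(seeds), dim(image)) && !all(seeds %in% c(0, 1))) {
    return(assert_membership(seeds, image))  # an existing membership field
  }
  init_membership(image, seeds)
}

new_segmentation <- function(u, trace, iterations, converged, params) {
  structure(list(membership = u,
                 binary_mask = u > 0.5,
                 energy_trace = as.numeric(trace),
                 iterations_run = iterations,
                 converged = converged,
                 params = params),
            class = "fuzzac_segmentation")
}

#' @export
print.fuzzac_segmentation <- function(x, ...) {
  cat("fuzzy active contour segmentation (", x$params$model, " model)\n",
      sep = "")
  cat("  ", nrow(x$membership), "x", ncol(x$membership), "pixels;",
      sum(x$binary_mask), "foreground\n")
  cat("  iterations:", x$iterations_run,
      if (x$converged) "(converged)" else "(max iterations reached)", "\n")
  cat("  energy:", format(x$energy_trace[1]), "->",
      format(x$energy_trace[length(x$energy_trace)]), "\n")
  invisible(x)
}

#' Export an energy trace as CSV
#'
#' Two columns, `iteration` (0 = initial state) and `energy`.
#'
#' @param result A `fuzzac_segmentation` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_trace <- function(result, path) {
  df <- data.frame(iteration = seq_along(result$energy_trace) - 1L,
                   energy = result$energy_trace)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
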