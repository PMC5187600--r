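# Global fuzzy energy-based active contour (FEAC) baseline.
#
# Same pseudo-level-set representation and direct sweep optimizer as the
# localized model, but with a single pair of whole-image prototypes
#   c1 = sum u^m I / sum u^m,   c2 = sum (1-u)^m I / sum (1-u)^m
# and the energy
#   F = lambda1 sum u^m (I-c1)^2 + lambda2 sum (1-u)^m (I-c2)^2
#       + mu * Length(C).
# The closed-form single-pixel update rules are the patch formulas with the
# patch equal to the whole image, so the localized model with a radius at
# least the image diagonal reproduces this baseline exactly (with unit
# weights and mu = 0).

#' Parameters for the global FEAC baseline
#'
#' @param lambda1,lambda2 Positive class weights (default 1, the values used
#'   in the comparison experiments).
#' @param mu Length-term weight (>= 0; default 0 — the comparisons are run
#'   without a length penalty).  The discrete length surrogate is the count
#'   of 4-neighbor edges crossing the 0.5 threshold.
#' @param m Fuzzifier exponent (> 1; default 2).
#' @param max_iterations,band_width,energy_tolerance As in [model_params()].
#' @return Validated parameter list of class `feac_params`.
#' @export
feac_params <- function(lambda1 = 1, lambda2 = 1, mu = 0, m = 2,
                        max_iterations = 200L, band_width = 2L,
                        energy_tolerance = 1e-10) {
  if (lambda1 <= 0 || lambda2 <= 0) stop_validation("lambda weights must be > 0")
  if (mu < 0) stop_validation("mu must be >= 0")
  assert_fuzzifier(m)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, m = m,
                 max_iterations = as.integer(max_iterations),
                 band_width = as.integer(band_width),
                 energy_tolerance = energy_tolerance, model = "feac"),
            class = "feac_params")
}

#' Whole-image fuzzy prototypes
#'
#' Membership-weighted global mean intensities of the foreground and
#' background classes.  An empty class falls back to the global mean.
#'
#' @param image Intensity matrix.
#' @param u Membership matrix.
#' @param m Fuzzifier exponent.
#' @return List with scalars `c1`, `c2`, `s1`, `s2`.
#' @export
feac_global_prototypes <- function(image, u, m = 2) {
  assert_image(image)
  assert_membership(u, image)
  um <- u^m
  vm <- (1 - u)^m
  s1 <- sum(um); s2 <- sum(vm)
  gmean <- mean(image)
  list(c1 = if (s1 > 0) sum(um * image) / s1 else gmean,
       c2 = if (s2 > 0) sum(vm * image) / s2 else gmean,
       s1 = s1, s2 = s2)
}

#' FEAC membership candidate
#'
#' \deqn{u = 1 / (1 + (\lambda_1 (I-c_1)^2 / (\lambda_2 (I-c_2)^2))^{1/(m-1)})}
#' with the same zero-distance limit conventions as
#' [membership_candidate()]; with `lambda1 == lambda2` the two functions
#' coincide.
#'
#' @param intensity Pixel intensity.
#' @param c1,c2 Global prototypes.
#' @param lambda1,lambda2 Class weights.
#' @param m Fuzzifier exponent.
#' @return Membership in \[0, 1\]; vectorized.
#' @export
feac_membership <- function(intensity, c1, c2, lambda1 = 1, lambda2 = 1,
                            m = 2) {
  assert_fuzzifier(m)
  d1 <- lambda1 * (intensity - c1)^2
  d2 <- lambda2 * (intensity - c2)^2
  ratio <- (d1 / d2)^(1 / (m - 1))
  un <- 1 / (1 + ratio)
  un[d1 == 0 & d2 == 0] <- 0.5
  un[d1 == 0 & d2 > 0] <- 1
  un[d2 == 0 & d1 > 0] <- 0
  un[!is.finite(ratio) & d2 > 0 & d1 > 0] <- 0
  un
}

# Global FEAC energy (with optional length penalty).
feac_energy <- function(image, u, c1, c2, lambda1 = 1, lambda2 = 1, mu = 0,
                        m = 2) {
  f <- lambda1 * sum(u^m * (image - c1)^2) +
       lambda2 * sum((1 - u)^m * (image - c2)^2)
  if (mu > 0) f <- f + mu * perimeter_cpp(u)
  f
}

#' Segment an image with the global FEAC baseline
#'
#' Same narrow-band sweep architecture as [segment()], with whole-image
#' prototypes maintained by the scalar form of the incremental update and
#' the global-energy closed-form change per single-pixel move.
#'
#' @param image Intensity matrix in \[0, 1\].
#' @param seeds Seed regions as in [init_membership()], or an existing
#'   membership matrix.
#' @param params A [feac_params()] list.
#' @return A `fuzzac_segmentation` object (see [segment()]).
#' @export
feac_segment <- function(image, seeds, params = feac_params()) {
  assert_image(image)
  u <- as_initial_membership(image, seeds)
  gp <- feac_global_prototypes(image, u, params$m)
  f0 <- feac_energy(image, u, gp$c1, gp$c2, params$lambda1, params$lambda2,
                    params$mu, params$m)
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
    res <- feac_sweep_cpp(image, u + 0, gp$s1, gp$s2, gp$c1, gp$c2,
                          band$pixels - 1L, params$m,
                          params$lambda1, params$lambda2, params$mu)
    it <- it + 1L
    u <- res$u
    gp <- list(c1 = res$c1, c2 = res$c2, s1 = res$s1, s2 = res$s2)
    f <- f + res$delta_f
    trace <- c(trace, f)
    if (res$accepted == 0L || abs(res$delta_f) < tol) {
      converged <- TRUE
      break
    }
    if (it %% 50L == 0L) gp <- feac_global_prototypes(image, u, params$m)
  }
  new_segmentation(u, trace, it, converged, params)
}
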