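# Patch-local fuzzy energies and the closed-form incremental update rules.
#
# The model: the contour is the 0.5-level of a fuzzy membership field u.
# Each pixel x carries a disc patch of radius r with its own pair of
# membership-weighted intensity prototypes
#   c1(x) = sum_y W(x,y) u(y)^m I(y) / s1(x),  s1(x) = sum_y W(x,y) u(y)^m
#   c2(x) = sum_y W(x,y) (1-u(y))^m I(y) / s2(x)
# and the total energy is the sum over all patches of the fuzzy fitting
# residuals.  No length/regularization term is used in the localized model.

#' Patch-local fuzzy statistics at every pixel
#'
#' Computes the four per-pixel maps s1, s2 (membership-weighted patch masses)
#' and c1, c2 (local foreground/background intensity prototypes) for a disc
#' patch clipped to the image.  Where a patch contains no mass of one class
#' (s1 = 0 or s2 = 0) the corresponding prototype falls back to the
#' unweighted patch mean intensity, which keeps the membership candidate
#' evaluable while contributing nothing to the energy.
#'
#' @param image Intensity matrix in \[0, 1\].
#' @param u Membership matrix, same shape.
#' @param mask A [make_disc_mask()] patch mask.
#' @param m Fuzzifier exponent, > 1.
#' @return An object of class `local_statistics`: list of matrices
#'   `s1`, `s2`, `c1`, `c2`, plus the `radius` and `m` used.
#' @export
compute_local_statistics <- function(image, u, mask, m = 2) {
  assert_image(image)
  assert_membership(u, image)
  assert_fuzzifier(m)
  st <- local_stats_cpp(image, u, mask$offsets, m)
  structure(c(st, list(radius = mask$radius, m = m)),
            class = "local_statistics")
}

assert_fuzzifier <- function(m) {
  if (length(m) != 1L || is.na(m) || m <= 1)
    stop_validation("fuzzifier m must be > 1")
  invisible(m)
}

#' Total localized patch energy
#'
#' Direct evaluation of
#' \deqn{F = \sum_x \sum_y W(x,y)\,[\,u(y)^m (I(y)-c_1(x))^2 +
#'   (1-u(y))^m (I(y)-c_2(x))^2\,]}
#' using the prototype maps in `stats`.  No regularization term is added.
#'
#' @inheritParams compute_local_statistics
#' @param stats Local statistics consistent with `(image, u, mask, m)`.
#' @return The scalar energy F (>= 0).
#' @export
total_localized_energy <- function(image, u, stats, mask, m = 2) {
  assert_image(image)
  assert_membership(u, image)
  total_energy_cpp(image, u, stats$c1, stats$c2, mask$offsets, m)
}

#' Optimal membership for one pixel given fixed prototypes
#'
#' The unconstrained minimizer of the fuzzy fitting energy in a single
#' membership value:
#' \deqn{u_n = \frac{1}{1 + ((I_0-c_1)^2 / (I_0-c_2)^2)^{1/(m-1)}}.}
#' Limits are explicit: `I0 == c1` (and not `c2`) gives 1, `I0 == c2`
#' gives 0, and `I0 == c1 == c2` gives 0.5.
#'
#' @param intensity Pixel intensity I0.
#' @param c1,c2 Foreground/background prototypes.
#' @param m Fuzzifier exponent, > 1.
#' @return Membership value in \[0, 1\].  Vectorized over its arguments.
#' @export
membership_candidate <- function(intensity, c1, c2, m = 2) {
  assert_fuzzifier(m)
  d1 <- (intensity - c1)^2
  d2 <- (intensity - c2)^2
  ratio <- (d1 / d2)^(1 / (m - 1))
  un <- 1 / (1 + ratio)
  un[d1 == 0 & d2 == 0] <- 0.5
  un[d1 == 0 & d2 > 0] <- 1
  un[d2 == 0 & d1 > 0] <- 0
  un[!is.finite(ratio) & d2 > 0 & d1 > 0] <- 0
  un
}

#' Closed-form prototype update after a single membership change
#'
#' When the membership of one pixel P (intensity `I0`) inside a patch
#' changes from `u0` to `u_n`, the patch prototypes move by
#' \deqn{\hat c_1 = c_1 + \frac{u_n^m - u_0^m}{s_1 + u_n^m - u_0^m}(I_0 - c_1)}
#' (and analogously for \eqn{c_2} with the complements), with the masses
#' updated by the same increments.  This is exact — no re-summation over the
#' patch is needed — and is what makes the direct sweep optimizer fast.
#'
#' @param s1,s2 Current patch masses (P's contribution included).
#' @param c1,c2 Current patch prototypes.
#' @param u0 Old membership at P; `u_n` the new one.
#' @param u_n New membership at P.
#' @param I0 Intensity at P.
#' @param m Fuzzifier exponent, > 1.
#' @return List with `c1`, `c2`, `s1`, `s2` (updated), or a
#'   `degenerate = TRUE` flag when an update would empty one class
#'   (denominator <= 0); the caller then recomputes or skips.
#' @export
incremental_prototype_update <- function(s1, s2, c1, c2, u0, u_n, I0, m = 2) {
  assert_fuzzifier(m)
  du1 <- u_n^m - u0^m
  du2 <- (1 - u_n)^m - (1 - u0)^m
  d1 <- s1 + du1
  d2 <- s2 + du2
  if (d1 <= 1e-12 || d2 <= 1e-12)
    return(list(degenerate = TRUE, c1 = c1, c2 = c2, s1 = s1, s2 = s2))
  list(degenerate = FALSE,
       c1 = c1 + du1 / d1 * (I0 - c1),
       c2 = c2 + du2 / d2 * (I0 - c2),
       s1 = d1, s2 = d2)
}

#' Exact energy change for a single-pixel membership change
#'
#' Computes, without re-evaluating the energy, the total change
#' \deqn{\Delta F = \sum_x \Big[ s_1(x)\frac{u_n^m - u_0^m}{s_1(x)+u_n^m-u_0^m}
#'   (I_0 - c_1(x))^2 + s_2(x)\frac{(1-u_n)^m - (1-u_0)^m}
#'   {s_2(x)+(1-u_n)^m-(1-u_0)^m}(I_0 - c_2(x))^2 \Big]}
#' where x ranges over exactly the patch centers whose footprint contains
#' the changed pixel (all other patches are untouched, so their terms are
#' identically zero).  Degenerate centers are evaluated directly from the
#' membership field as a fallback.
#'
#' @param image,u Current image and membership field.
#' @param stats Current [compute_local_statistics()] output.
#' @param mask The patch mask.
#' @param point `c(row, col)` of the changed pixel (1-based).
#' @param u_n Proposed new membership at `point`.
#' @param m Fuzzifier exponent, > 1.
#' @return List with `delta_f`, the affected `center_row`/`center_col`
#'   vectors, their updated `s1`, `s2`, `c1`, `c2`, and `n_degenerate`.
#' @export
energy_change <- function(image, u, stats, mask, point, u_n, m = 2) {
  assert_image(image)
  assert_membership(u, image)
  assert_fuzzifier(m)
  if (length(point) != 2L || any(point < 1) ||
      point[1] > nrow(image) || point[2] > ncol(image))
    stop_validation("point must be c(row, col) inside the image")
  energy_change_cpp(image, u, stats$s1, stats$s2, stats$c1, stats$c2,
                    mask$offsets, m,
                    as.integer(point[1]) - 1L, as.integer(point[2]) - 1L,
                    u_n)
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{D = 2|A \cap B| / (|A| + |B|)}; 1 is a perfect match.  Two empty
#' masks count as a perfect match (D = 1).
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of the same shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  assert_same_shape(mask_a, mask_b, "masks")
  a <- mask_a > 0
  b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
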