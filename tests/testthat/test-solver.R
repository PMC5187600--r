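test_that("narrow band is the dilated 0.5-transition set", {
  # half-plane step: columns k-1..k for band_width 1
  u <- matrix(0, 10, 10); u[, 1:4] <- 1
  nb <- extract_narrow_band(u, 1)
  expect_setequal(unique(nb$pixels[, "col"]), c(4, 5))
  expect_equal(nrow(nb$pixels), 20)
  # raster order: sorted by row, then column
  expect_false(is.unsorted(nb$pixels[, "row"]))

  # wider band picks up two columns each side
  nb2 <- extract_narrow_band(u, 2)
  expect_setequal(unique(nb2$pixels[, "col"]), 3:6)

  # no contour -> empty band
  expect_equal(nrow(extract_narrow_band(matrix(1, 5, 5), 1)$pixels), 0)
  expect_equal(nrow(extract_narrow_band(matrix(0.2, 5, 5), 2)$pixels), 0)

  # single-pixel island: the island plus its 8-neighborhood
  ui <- matrix(0, 9, 9); ui[5, 5] <- 1
  nbi <- extract_narrow_band(ui, 1)
  expect_equal(nrow(nbi$pixels), 9)
  expect_true(all(abs(nbi$pixels[, 1] - 5) <= 1 & abs(nbi$pixels[, 2] - 5) <= 1))
})

test_that("model parameters are validated", {
  p <- model_params()
  expect_equal(p$radius, 20L)
  expect_equal(p$m, 2)
  expect_equal(p$max_iterations, 200L)
  expect_error(model_params(radius = 0), "radius")
  expect_error(model_params(m = 1), "m")
  expect_error(model_params(band_width = 0), "band_width")
  expect_error(model_params(model = "banana"))
})

test_that("a sweep from a zero-energy optimum accepts nothing", {
  fx <- two_region_fixture(24)
  params <- model_params(radius = 4)
  mk <- make_disc_mask(4)
  st <- compute_local_statistics(fx$I, fx$u, mk, 2)
  band <- extract_narrow_band(fx$u, 2)
  sw <- sweep_iteration(fx$I, fx$u, st, band, params, mk)
  expect_equal(sw$accepted, 0L)
  expect_equal(sw$delta_f, 0)
  expect_identical(sw$u, fx$u)
})

test_that("sweep energy bookkeeping matches a direct recomputation", {
  set.seed(4)
  I <- matrix(runif(400), 20, 20)
  u0 <- init_membership(I, list(c(6, 6, 8, 8)))
  mk <- make_disc_mask(3)
  params <- model_params(radius = 3)
  st <- compute_local_statistics(I, u0, mk, 2)
  f0 <- total_localized_energy(I, u0, st, mk, 2)
  band <- extract_narrow_band(u0, 2)
  sw <- sweep_iteration(I, u0, st, band, params, mk)
  expect_gt(sw$accepted, 0L)
  expect_lte(sw$delta_f, 0)
  st_fresh <- compute_local_statistics(I, sw$u, mk, 2)
  f1 <- total_localized_energy(I, sw$u, st_fresh, mk, 2)
  expect_lt(abs(sw$delta_f - (f1 - f0)) / abs(f1 - f0), 1e-8)
})

test_that("incrementally maintained statistics stay consistent over sweeps", {
  set.seed(8)
  I <- matrix(runif(30 * 30), 30, 30)
  u <- init_membership(I, list(c(8, 8, 14, 14)))
  mk <- make_disc_mask(4)
  params <- model_params(radius = 4)
  st <- compute_local_statistics(I, u, mk, 2)
  for (k in 1:5) {
    band <- extract_narrow_band(u, 2)
    if (nrow(band$pixels) == 0L) break
    sw <- sweep_iteration(I, u, st, band, params, mk)
    u <- sw$u; st <- sw$stats
  }
  fresh <- compute_local_statistics(I, u, mk, 2)
  expect_lt(max(abs(st$s1 - fresh$s1)), 1e-8)
  expect_lt(max(abs(st$s2 - fresh$s2)), 1e-8)
  expect_lt(max(abs(st$c1 - fresh$c1)), 1e-8)
  expect_lt(max(abs(st$c2 - fresh$c2)), 1e-8)
})

test_that("a single misclassified interior pixel is repaired in one sweep", {
  fx <- two_region_fixture(24)
  u <- fx$u
  # flip a foreground pixel just inside the boundary, so that its patch
  # contains both classes (a wrong label deep inside a constant region is
  # energetically invisible: it becomes its own prototype)
  u[12, 16] <- 0
  stopifnot(fx$truth[12, 16])
  mk <- make_disc_mask(4)
  params <- model_params(radius = 4)
  st <- compute_local_statistics(fx$I, u, mk, 2)
  band <- extract_narrow_band(u, 2)
  sw <- sweep_iteration(fx$I, u, st, band, params, mk)
  expect_gt(sw$accepted, 0L)
  expect_equal(dice_coefficient(sw$u > 0.5, fx$truth), 1)
})

test_that("segment recovers a clean two-region phantom and behaves sanely", {
  ph <- generate_phantom(phantom_spec(
    48, 48,
    shapes = list(list(kind = "circle", center = c(24, 24), radius = 12,
                       level = 0.8)),
    background_level = 0.2))
  res <- segment(ph$image, list(c(6, 6, 36, 36)),
                 model_params(radius = 10, max_iterations = 100))
  expect_s3_class(res, "fuzzac_segmentation")
  expect_gte(dice_coefficient(res$binary_mask, ph$truth), 0.99)
  expect_true(res$converged)
  expect_lt(res$iterations_run, 100)
  # energy trace is non-increasing, and the mask is exactly membership > 0.5
  expect_true(all(diff(res$energy_trace) <= 0))
  expect_identical(res$binary_mask, res$membership > 0.5)

  # determinism: identical inputs give bit-identical results
  res2 <- segment(ph$image, list(c(6, 6, 36, 36)),
                  model_params(radius = 10, max_iterations = 100))
  expect_identical(res$membership, res2$membership)
  expect_identical(res$energy_trace, res2$energy_trace)
})

test_that("degenerate starts are handled as documented", {
  ph <- generate_phantom(phantom_spec(
    32, 32,
    shapes = list(list(kind = "circle", center = c(16, 16), radius = 8,
                       level = 0.8)),
    background_level = 0.2))

  # max_iterations = 0 returns the initial partition, not converged
  res0 <- segment(ph$image, list(c(4, 4, 24, 24)),
                  model_params(radius = 5, max_iterations = 0))
  expect_false(res0$converged)
  expect_equal(res0$iterations_run, 0L)
  expect_equal(sum(res0$binary_mask), 24 * 24)

  # a full-image seed has no contour: warning, initial partition returned
  expect_warning(
    resw <- segment(ph$image, list(c(1, 1, 32, 32)),
                    model_params(radius = 5, max_iterations = 10)),
    "contour")
  expect_true(all(resw$binary_mask))
  expect_equal(resw$iterations_run, 0L)
})

test_that("energy trace CSV export round-trips", {
  tmp <- withr::local_tempdir()
  fx <- two_region_fixture(24)
  res <- segment(fx$I, list(c(4, 4, 16, 16)),
                 model_params(radius = 4, max_iterations = 30))
  p <- file.path(tmp, "trace.csv")
  write_energy_trace(res, p)
  df <- read.csv(p)
  expect_equal(df$iteration, seq_along(res$energy_trace) - 1L)
  expect_equal(df$energy, res$energy_trace)
})
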