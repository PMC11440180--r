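test_that("normalized amplitudes: arithmetic, null component, rescale invariance", {
  expect_equal(unname(normalize_amplitudes(c(2, 1), c(1, 0.2), c(0, 1))),
               c(0.5, 0.25, 0.25))
  n0 <- normalize_amplitudes(c(3, 1), c(2, 1), c(0, 0))
  expect_equal(unname(n0[["a_flavins"]]), 0)
  expect_equal(sum(n0), 1)
  set.seed(9)
  for (i in 1:100) {
    a1 <- runif(16); a2 <- runif(16); a3 <- runif(16)
    n <- normalize_amplitudes(a1, a2, a3)
    expect_equal(sum(n), 1, tolerance = 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(normalize_amplitudes(s * a1, s * a2, s * a3), n,
                 tolerance = 1e-12)
  }
  expect_error(normalize_amplitudes(0, 0, 0), "zero")
})

test_that("NAD(P)H mean lifetime from amplitudes", {
  # ratio 2.7 at tau_free 0.37, tau_bound 2.5
  expect_equal(nadh_mean_lifetime(2.7, 1, 0.37, 2.5),
               (2.7 * 0.37 + 2.5) / 3.7, tolerance = 1e-12)
  expect_equal(round(nadh_mean_lifetime(2.7, 1, 0.37, 2.5), 3), 0.946)
  expect_equal(nadh_mean_lifetime(0.3, 0, 0.37, 2.5), 0.37)
  expect_equal(nadh_mean_lifetime(1, 1, 1.3, 1.3), 1.3)
})

test_that("flavin lambda-average: point mass, symmetry, translation", {
  sp <- spectral_axis()
  s <- numeric(16)
  s[13] <- 2
  expect_equal(flavin_lambda_avg(s, sp), sp$channel_centers_nm[13])
  sym <- numeric(16)
  sym[c(11, 13)] <- 1
  expect_equal(flavin_lambda_avg(sym, sp), sp$channel_centers_nm[12])
  # red-shift of a compactly supported spectrum by one channel moves
  # lambda_avg by exactly one channel spacing
  spec <- numeric(16)
  spec[11:14] <- c(0.3, 1, 0.7, 0.2)
  shifted <- c(0, spec[-16])
  spacing <- diff(sp$channel_centers_nm)[1]
  expect_equal(flavin_lambda_avg(shifted, sp) - flavin_lambda_avg(spec, sp),
               spacing, tolerance = 1e-9)
  expect_true(is.na(flavin_lambda_avg(numeric(16), sp)))
})

test_that("noiseless global inversion recovers the generating parameters within 1%", {
  im <- default_instrument()
  b <- default_basis(im)
  M <- expected_cell_decays(control_truth(), im, b, 5e5)
  g <- fit_global(M, im, b)
  expect_lt(abs(g$tau_bound_ns / 2.5 - 1), 0.01)
  expect_lt(abs(g$tau_flavin_ns / 1.48 - 1), 0.01)
  expect_lt(abs(g$ratio_free_bound / 2.7 - 1), 0.01)
  expect_lt(abs(g$a_flavins / 0.12 - 1), 0.01)
  expect_equal(g$a_free + g$a_bound + g$a_flavins, 1, tolerance = 1e-9)
  # constraint enforcement
  expect_identical(g$tau_free_ns, 0.37)
  expect_true(all(g$flavin_spectrum[
    b$spectral$channel_centers_nm < 490] == 0))
  expect_true(g$tau_bound_ns >= b$tau_bound_bounds_ns[1] &&
              g$tau_bound_ns <= b$tau_bound_bounds_ns[2])
})

test_that("data without flavins yield a near-zero flavin amplitude", {
  im <- default_instrument()
  b <- default_basis(im)
  truth <- control_truth()
  truth$flavin_fraction <- 0
  M <- expected_cell_decays(truth, im, b, 5e5)
  set.seed(77)
  g <- fit_global(matrix(rpois(length(M), M), nrow(M)), im, b)
  expect_lt(g$a_flavins, 0.02)
})

test_that("nested two-component fit agrees when the data hold no flavins", {
  im <- default_instrument()
  truth <- control_truth()
  truth$flavin_fraction <- 0
  b3 <- default_basis(im)
  # two-component basis: cutoff beyond the spectral range frees no flavin channel
  b2 <- component_basis(im$spectral, flavin_zero_below_nm = 1e4)
  M <- expected_cell_decays(truth, im, b3, 5e5)
  set.seed(13)
  for (i in 1:3) {
    Y <- matrix(rpois(length(M), M), nrow(M))
    g3 <- fit_global(Y, im, b3)
    g2 <- fit_global(Y, im, b2)
    expect_equal(g3$tau_bound_ns, g2$tau_bound_ns, tolerance = 0.02)
    expect_equal(g3$ratio_free_bound, g2$ratio_free_bound, tolerance = 0.05)
  }
})

test_that("recovered flavin fraction tracks the generated fraction", {
  im <- default_instrument()
  b <- default_basis(im)
  fr <- seq(0.05, 0.35, length.out = 10)
  set.seed(55)
  rec <- vapply(fr, function(f) {
    truth <- control_truth()
    truth$flavin_fraction <- f
    Y <- sim_cell_counts(truth, im, b, 1e5)
    fit_global(Y, im, b)$a_flavins
  }, 1)
  expect_gt(stats::cor(fr, rec), 0.95)
})

test_that("total-signal lambda-average grows monotonically with flavin fraction", {
  im <- default_instrument()
  b <- default_basis(im)
  lam <- vapply(seq(0, 0.4, by = 0.05), function(f) {
    truth <- control_truth()
    truth$flavin_fraction <- f
    M <- expected_cell_decays(truth, im, b, 1e5)
    I <- rowSums(M)
    sum(im$spectral$channel_centers_nm * I) / sum(I)
  }, 1)
  expect_true(all(diff(lam) > 0))
})

test_that("global fit guards its preconditions", {
  im <- default_instrument()
  b <- default_basis(im)
  expect_error(fit_global(matrix(0.1, 16, 256), im, b), "insufficient")
  M <- expected_cell_decays(control_truth(), im, b, 1e4)
  bad <- component_basis(spectral_axis(8, c(400, 500)))
  expect_error(fit_global(M, im, bad), "channels")
})
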