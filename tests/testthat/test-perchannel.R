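test_that("mean lifetime formula: worked example, identity, scale invariance", {
  expect_equal(mean_lifetime(0.80, 0.36, 0.20, 0.89), 0.466, tolerance = 1e-9)
  expect_equal(round(mean_lifetime(0.80, 0.36, 0.20, 0.89), 2), 0.47)
  expect_equal(mean_lifetime(1, 1.7, 0, 5), 1.7)
  expect_equal(mean_lifetime(8, 0.36, 2, 0.89),
               mean_lifetime(0.8, 0.36, 0.2, 0.89))
  expect_error(mean_lifetime(0, 1, 0, 1), "sum")
  expect_error(mean_lifetime(-0.1, 1, 0.5, 1), "non-negative")
})

test_that("noiseless bi-exponential curve is recovered within 1%", {
  im <- default_instrument()
  f <- fit_biexponential(free_nadh_curve(im), im)
  expect_lt(abs(f$a1 / 0.8 - 1), 0.01)
  expect_lt(abs(f$tau1_ns / 0.36 - 1), 0.01)
  expect_lt(abs(f$tau2_ns / 0.89 - 1), 0.01)
  expect_lt(abs(f$a2 / 0.2 - 1), 0.01)
  expect_equal(f$a1 + f$a2, 1, tolerance = 1e-9)
  expect_equal(f$tau_m_ns, f$a1 * f$tau1_ns + f$a2 * f$tau2_ns,
               tolerance = 1e-9)
})

test_that("mono-exponential input yields the degenerate fit with correct tau_m", {
  im <- default_instrument()
  m <- model_decay(1, 1.44, im)
  m <- m * 1e5 / sum(m)
  f <- fit_biexponential(m, im)
  expect_equal(f$tau_m_ns, 1.44, tolerance = 0.02 / 1.44)
  expect_lte(f$tau1_ns, f$tau2_ns)
})

test_that("Poisson replicates: parameter recovery, chi-square calibration, ordering", {
  im <- default_instrument()
  m <- free_nadh_curve(im, 1e5)
  set.seed(202)
  reps <- t(vapply(1:100, function(i) {
    f <- fit_biexponential(rpois(length(m), m), im)
    c(f$tau1_ns, f$a1, f$tau_m_ns, f$chi2_reduced, f$tau2_ns)
  }, numeric(5)))
  expect_lt(abs(mean(reps[, 1]) - 0.36), 0.02)   # tau1 bias
  expect_lt(abs(mean(reps[, 2]) - 0.80), 0.03)   # a1 bias
  expect_lt(abs(median(reps[, 3]) - 0.466), 0.03)
  expect_gt(median(reps[, 4]), 0.9)
  expect_lt(median(reps[, 4]), 1.1)
  expect_true(all(reps[, 1] <= reps[, 5]))       # tau1 <= tau2 always
})

test_that("insufficient photons raise an informative error", {
  im <- default_instrument()
  expect_error(fit_biexponential(rep(1, 256), im), "insufficient")
})

test_that("channel series reflects the spectral composition of the decays", {
  im <- default_instrument()
  b <- default_basis(im)
  set.seed(33)
  # NAD(P)H only: free fraction grows red-ward => tau_m non-increasing trend
  sp <- generate_component_spectra(im$spectral)
  amp <- rbind(3 * sp$free, 1 * sp$bound, rep(0, 16))
  M <- model_cube_slice(amp, c(0.37, 2.5, 1), im)
  M <- M * 2e6 / sum(M)
  cs <- fit_channel_series(matrix(rpois(length(M), M), nrow(M)), im)
  fit_ch <- which(is.na(cs$reason))
  tm <- cs$tau_m_ns[fit_ch]
  expect_lt(stats::cor(fit_ch, tm), 0)  # declining trend with wavelength

  # with flavins: non-monotonic, rising again above 490 nm
  M2 <- expected_cell_decays(
    list(ratio_free_bound = 2.7, tau_bound_ns = 2.5,
         flavin_fraction = 0.25, tau_flavin_ns = 1.48), im, b, 2e6)
  cs2 <- fit_channel_series(matrix(rpois(length(M2), M2), nrow(M2)), im)
  lam <- cs2$wavelength_nm
  red <- lam > 500 & is.na(cs2$reason)
  blue <- lam > 430 & lam < 490 & is.na(cs2$reason)
  expect_gt(max(cs2$tau_m_ns[red]), min(cs2$tau_m_ns[blue]))
  dip <- min(cs2$tau_m_ns[is.na(cs2$reason)])
  expect_gt(cs2$tau_m_ns[which(is.na(cs2$reason))[sum(is.na(cs2$reason))]], dip)
})

test_that("dead channels are reported missing without harming the rest", {
  im <- default_instrument()
  m <- free_nadh_curve(im, 5e4)
  M <- matrix(rep(m, each = 16), 16)
  M[7, ] <- 0
  set.seed(4)
  Mk <- matrix(rpois(length(M), M), 16)
  Mk[7, ] <- 0
  cs <- fit_channel_series(Mk, im)
  expect_equal(cs$reason[7], "below min_photons")
  expect_true(all(is.na(cs$tau_m_ns[7])))
  expect_true(all(!is.na(cs$tau_m_ns[-7])))
  expect_error(fit_channel_series(matrix(0, 16, 256), im), "all channels")
})
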