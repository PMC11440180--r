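test_that("time and spectral axes enforce their invariants", {
  tx <- time_axis(256, 12.5)
  expect_equal(tx$bin_width_ns, 12.5 / 256)
  expect_true(all(diff(tx$bin_centers_ns) > 0))
  expect_equal(diff(tx$bin_centers_ns),
               rep(tx$bin_width_ns, 255), tolerance = 1e-12)
  expect_error(time_axis(8), "16")
  expect_error(time_axis(256, -1), "positive")

  sp <- spectral_axis()
  expect_equal(sp$n_channels, 16L)
  expect_equal(sp$channel_centers_nm[1], 388.1)
  expect_equal(sp$channel_centers_nm[16], 573.6)
  expect_equal(unique(round(diff(sp$channel_centers_nm), 6)),
               round((573.6 - 388.1) / 15, 6))
  expect_error(spectral_axis(channel_centers_nm = c(500, 400)), "increasing")
})

test_that("gaussian IRF weights are normalized, centered and translation-covariant", {
  im <- default_instrument(irf_t0_ns = 2.0)
  w <- make_gaussian_irf(im)
  expect_length(w, 256)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # peak bin contains t0
  peak <- which.max(w)
  expect_equal(peak, findInterval(2.0, seq(0, 12.5, length.out = 257)))
  # FWHM -> sigma conversion
  expect_equal(im$irf_sigma_ns, 0.220 / 2.35482, tolerance = 1e-4)
  # a whole-bin t0 shift is a grid shift of the weights
  shift_bins <- 20L
  im3 <- default_instrument(irf_t0_ns = 2.0 + shift_bins * im$time$bin_width_ns)
  w3 <- make_gaussian_irf(im3)
  expect_equal(w3[(shift_bins + 1):256], w[1:(256 - shift_bins)],
               tolerance = 1e-9)
  # unresolvable IRF rejected
  expect_error(make_gaussian_irf(default_instrument(irf_fwhm_ns = 1e-4)),
               "unresolvable")
})

test_that("analytic model reduces to a delta-IRF exponential and is linear", {
  im <- default_instrument(irf_fwhm_ns = 1e-4 * 2.35482, wraparound = FALSE)
  t <- im$time$bin_centers_ns
  m <- model_decay(1, 1, im)
  ref <- ifelse(t >= im$irf_t0_ns, exp(-(t - im$irf_t0_ns)), 0)
  expect_lt(max(abs(m - ref)), 1e-6)

  im2 <- default_instrument()
  lhs <- model_decay(c(2, 3), c(0.8, 2.4), im2)
  rhs <- 2 * model_decay(1, 0.8, im2) + 3 * model_decay(1, 2.4, im2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(model_decay(1, -1, im2), "positive")
  expect_error(model_decay(-1, 1, im2), "non-negative")
})

test_that("analytic convolution matches the oversampled numeric oracle", {
  set.seed(101)
  for (i in 1:25) {
    tau <- runif(1, 0.2, 6)
    fwhm <- runif(1, 0.05, 0.3) * 2.35482
    im <- default_instrument(irf_fwhm_ns = fwhm)
    a <- model_decay(1, tau, im)
    n <- numeric_convolved_decay(1, tau, im)
    expect_lt(max(abs(a - n)) / max(a), 1e-4)
  }
})

test_that("larger lifetimes shift the model's time centroid later", {
  im <- default_instrument(wraparound = FALSE)
  t <- im$time$bin_centers_ns
  centroid <- function(tau) {
    m <- model_decay(1, tau, im)
    sum(t * m) / sum(m)
  }
  cs <- vapply(c(0.3, 0.8, 1.5, 2.5, 4), centroid, 1)
  expect_true(all(diff(cs) > 0))
})

test_that("wraparound conserves periodic mass independent of t0", {
  masses <- vapply(c(0.5, 2, 5, 9, 12), function(t0) {
    im <- default_instrument(irf_t0_ns = t0)
    sum(model_decay(1, 2.5, im)) * im$time$bin_width_ns
  }, 1)
  expect_equal(max(masses) / min(masses), 1, tolerance = 1e-6)
  # integrated mass equals amplitude * tau (unit-density Gaussian IRF)
  expect_equal(masses[1], 2.5, tolerance = 1e-3)
})

test_that("measured-IRF convolution path agrees with the analytic Gaussian path", {
  im <- default_instrument()
  im_meas <- default_instrument(irf_weights = make_gaussian_irf(im))
  t <- im$time$bin_centers_ns
  # a bin-resolution IRF cannot resolve the rising edge below the bin width,
  # so compare total mass and the curve away from the edge region
  away <- abs(t - im$irf_t0_ns) > 6 * im$irf_sigma_ns
  for (tau in c(0.37, 1.48, 2.5)) {
    a <- model_decay(1, tau, im)
    d <- model_decay(1, tau, im_meas)
    expect_equal(sum(d), sum(a), tolerance = 2e-3)
    expect_lt(max(abs(a[away] - d[away])) / max(a), 5e-3)
  }
})

test_that("model_cube_slice distributes shared lifetimes over channels", {
  im <- default_instrument()
  amp <- rbind(runif(16), runif(16), c(rep(0, 8), runif(8)))
  taus <- c(0.37, 2.5, 1.48)
  M <- model_cube_slice(amp, taus, im)
  expect_equal(dim(M), c(16L, 256L))
  # each channel equals model_decay with that channel's amplitudes
  for (c in c(1, 9, 16))
    expect_equal(M[c, ], model_decay(amp[, c], taus, im), tolerance = 1e-12)
  # channel sum equals model with channel-summed amplitudes (linearity)
  expect_equal(colSums(M), model_decay(rowSums(amp), taus, im),
               tolerance = 1e-9)
  # removing the flavin component reduces to the two-component model
  amp0 <- amp
  amp0[3, ] <- 0
  M0 <- model_cube_slice(amp0, taus, im)
  M2 <- model_cube_slice(amp0[1:2, , drop = FALSE], taus[1:2], im)
  expect_equal(M0, M2, tolerance = 1e-12)
  expect_error(model_cube_slice(amp[, 1:5], taus, im), "channels")
})

test_that("decay_curve and spectral_cube validate their contents", {
  im <- default_instrument()
  dc <- decay_curve(rep(1, 256), im$time)
  expect_equal(dc$total_photons, 256)
  expect_error(decay_curve(rep(-1, 256), im$time), "non-negative")
  expect_error(decay_curve(rep(1, 10), im$time), "length")
  expect_error(spectral_cube(array(1, c(2, 2, 3, 256)), im), "channels")
})
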