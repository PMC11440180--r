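test_that("component spectra peak at the right channels and obey the cutoff", {
  sp <- spectral_axis()
  s <- generate_component_spectra(sp)
  lam <- sp$channel_centers_nm
  # argmax channels are the grid channels nearest 475 / 450 / 535 nm
  expect_equal(which.max(s$free), which.min(abs(lam - 475)))
  expect_equal(which.max(s$bound), which.min(abs(lam - 450)))
  expect_equal(which.max(s$flavin), which.min(abs(lam - 535)))
  expect_true(all(s$flavin[lam < 490] == 0))
  expect_equal(max(s$free), 1)
  expect_equal(max(s$bound), 1)
  expect_equal(max(s$flavin), 1)
  # +15 nm flavin peak shift moves lambda_avg by about +15 nm
  s2 <- generate_component_spectra(sp, flavin_peak_nm = 550)
  d <- flavin_lambda_avg(s2$flavin, sp) - flavin_lambda_avg(s$flavin, sp)
  expect_lt(abs(d - 15), diff(lam)[1])
  expect_error(generate_component_spectra(sp, flavin_peak_nm = 700),
               "outside")
})

test_that("group scenes carry the group's median ground truth", {
  ph <- make_group_scene("control", 120, seed = 5)
  expect_equal(sort(unique(as.vector(ph$cell_masks[ph$cell_masks > 0]))),
               1:120)
  expect_equal(nrow(ph$truth), 120)
  # medians near the group targets (CV 10%, n = 120)
  expect_equal(median(ph$truth$ratio_free_bound), 2.7, tolerance = 0.05)
  expect_equal(median(ph$truth$tau_bound_ns), 2.5, tolerance = 0.05)
  rot <- make_group_scene("rotenone", 120, seed = 6)
  expect_lt(median(rot$truth$flavin_fraction),
            median(ph$truth$flavin_fraction))
  expect_error(make_group_scene("mystery", 10, seed = 1), "unknown group")
  # the three acquisition-sized scenes hold 754 cells in total
  counts <- vapply(list(c("control", 251), c("rotenone", 285), c("3BP", 218)),
                   function(x) {
                     p <- make_group_scene(x[1], as.integer(x[2]), seed = 1)
                     max(p$cell_masks)
                   }, 1)
  expect_equal(sum(counts), 754)
})

test_that("spheroid phantom profiles are linear, monotone and span the depth range", {
  ph <- make_spheroid_scene(seed = 8)
  tr <- ph$truth
  expect_lt(min(tr$border_distance_um), 5)
  expect_gt(max(tr$border_distance_um), 80)
  shell <- tr[which.min(tr$border_distance_um), ]
  core <- tr[tr$border_distance_um >= 80, ][1, ]
  expect_equal(shell$ratio_free_bound, 5.3, tolerance = 0.02)
  expect_equal(core$ratio_free_bound, 4.0, tolerance = 1e-9)
  expect_equal(core$flavin_fraction, 0.16, tolerance = 1e-9)
  # monotone by construction
  o <- order(tr$border_distance_um)
  expect_true(all(diff(tr$ratio_free_bound[o]) <= 1e-12))
  expect_true(all(diff(tr$flavin_fraction[o]) >= -1e-12))
  # implied tau_m gradient spans 0.84 -> 0.86 ns
  tau_m <- (tr$ratio_free_bound * 0.37 + tr$tau_bound_ns) /
    (tr$ratio_free_bound + 1)
  expect_equal(min(tau_m), 0.84, tolerance = 1e-3)
  expect_equal(max(tau_m), 0.86, tolerance = 1e-3)
})

test_that("cube simulation is seeded, budgeted and dark where unlabelled", {
  im <- default_instrument()
  b <- default_basis(im)
  ph <- make_group_scene("control", 4, seed = 3)
  c1 <- simulate_cube(ph, im, b, seed = 21)
  c2 <- simulate_cube(ph, im, b, seed = 21)
  expect_identical(c1$counts, c2$counts)
  c3 <- simulate_cube(ph, im, b, seed = 22)
  expect_false(identical(c1$counts, c3$counts))
  # background pixels are exactly empty without a dark-count rate
  bg <- which(ph$cell_masks == 0)
  cm <- matrix(c1$counts, prod(dim(ph$cell_masks)), 16 * 256)
  expect_true(all(cm[bg, ] == 0))
  # total counts meet the requested budget within Poisson error
  budget <- 2e5
  cb <- simulate_cube(ph, im, b, seed = 23, total_photon_budget = budget)
  expect_lt(abs(sum(cb$counts) - budget), 3 * sqrt(budget))
  expect_error(simulate_cube(ph, im, b), "seed")
})
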