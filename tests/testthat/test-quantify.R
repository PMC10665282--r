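test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(5, 1000, elapsed_s = 0), 5)
  expect_equal(decay_correct(5, 1000, elapsed_s = 1000), 2.5)
  expect_equal(decay_correct(5, 1000, elapsed_s = -1000), 10)
  # one year of Ba-133 decay from the tabulated C4 activity
  expect_equal(decay_correct(10304, ba133(), elapsed_s = 365.25 * 86400),
               9645.757, tolerance = 1e-6)
  # POSIXct interface
  t0 <- as.POSIXct("2018-12-15 12:00:00", tz = "UTC")
  expect_equal(decay_correct(10304, ba133(), from = t0, to = t0 + 365.25 * 86400),
               10304 * 2^(-1 / 10.5), tolerance = 1e-12)
  expect_error(decay_correct(1, 10, elapsed_s = NaN), "finite")
})

test_that("calibration factors and their uncertainty budget are computed per the protocol", {
  expect_equal(icf(0, 1800, 1)$value, 0)
  r <- icf(72000, 1800, 1.0)
  expect_equal(r$value, 40)
  expect_error(icf(100, 0, 1), "division")
  expect_error(icf(100, 1800, 0), "division")

  # Poisson + timing terms only: sqrt(1/1e4 + (1/1800)^2) ~ 1.0015%
  expect_equal(icf_uncertainty(1e4, 1800), sqrt(1e-4 + (1 / 1800)^2))
  expect_equal(icf(1e4, 1800, 1)$u_rel, sqrt(1e-4 + (1 / 1800)^2))

  # Poisson floor: u >= value / sqrt(C)
  expect_gte(r$u, r$value / sqrt(r$counts))

  # published solid-source budget: 1.0%, 0.4%, 0.06% in quadrature -> 1.1%
  cmi <- activity_measurement(1, u_calibration = 0.010,
                              u_statistical = 0.004,
                              u_weighing_halfwidth = 0.0006)
  expect_equal(signif(100 * activity_uncertainty(cmi), 2), 1.1)

  # rectangular component enters divided by sqrt(3)
  rectonly <- activity_measurement(1, u_weighing_halfwidth = 0.03)
  expect_equal(activity_uncertainty(rectonly), 0.03 / sqrt(3))

  # more counts at a fixed budget strictly decreases u
  expect_lt(icf_uncertainty(2e4, 1800, cmi), icf_uncertainty(1e4, 1800, cmi))
  expect_error(icf_uncertainty(0, 1800), "budget")

  # activity measurement object flows into the ICF budget
  ri <- icf(1e6, 1800, 2, activity_u_rel = cmi)
  expect_equal(ri$u_rel,
               sqrt(1 / 1e6 + (1 / 1800)^2 + activity_uncertainty(cmi)^2))
})

test_that("dual-source combination averages and inflates for deviation", {
  # equal inputs: mean unchanged, u = u0/sqrt(2)
  eq <- combine_dual_source(40, 40, u_a = 0.6, u_b = 0.6)
  expect_equal(eq$mean, 40)
  expect_equal(eq$u, 0.6 / sqrt(2))

  # zero component uncertainties with deviation 4: u = 4/sqrt(12)
  dv <- combine_dual_source(40, 44, u_a = 0, u_b = 0)
  expect_equal(dv$mean, 42)
  expect_equal(dv$u, 4 / sqrt(12))

  # symmetric in its inputs; u non-decreasing in |a - b|
  sw <- combine_dual_source(44, 40, u_b = 0, u_a = 0)
  expect_equal(sw$mean, dv$mean)
  expect_equal(sw$u, dv$u)
  us <- vapply(seq(0, 8, by = 0.5), function(d)
    combine_dual_source(40, 40 + d, u_a = 0.3, u_b = 0.4)$u, 0)
  expect_true(all(diff(us) >= 0))

  # mismatched cylinders refuse to pair
  a <- icf(1000, 1800, 1, cylinder = "C1")
  b <- icf(1000, 1800, 1, cylinder = "C2")
  expect_error(combine_dual_source(a, b), "pairing")
})

test_that("stock-solution activities reproduce the dispensed values", {
  expect_equal(signif(cylinder_activity_from_stock(0.18, 107.4)$activity_MBq, 2), 19)
  expect_equal(signif(cylinder_activity_from_stock(0.18, 6.72)$activity_MBq, 2), 1.2)
  expect_equal(cylinder_activity_from_stock(0.18, 1)$activity_MBq, 0.18)
  expect_equal(cylinder_activity_from_stock(1, 1, 0.03, 0.04)$u_rel, 0.05)
})

test_that("the ICF estimator is unbiased on the uniform phantom and pseudo-ICFs sit below it", {
  # uniform Jaszczak phantom, enlarged VOI, 50 seeds
  av <- spectcal:::uniform_phantom_volume(39.9, voxel_size = 6,
                                          supersample = 4L)
  sys <- system_model(60, psf_fwhm = 20)
  jasz <- cylinder_spec("JASZ", 216, 186)
  vals <- numeric(50); us <- numeric(50)
  for (s in 1:50) {
    img <- simulate_count_image(av, sys, i131(), 3600, seed = s)
    base <- nominal_geometry_voi(img, jasz)
    big <- enlarged_voi(img, base, 40)
    r <- icf(voi_counts(img, big), 3600, 39.9, activity_u_rel = 0.01,
             kind = "ICF")
    vals[s] <- r$value; us[s] <- r$u
  }
  truth <- true_icf(sys, i131())
  expect_lt(abs(mean(vals) - truth), 2 * mean(us))

  # partial-volume ordering: pseudo-ICF (matched VOI) < ICF (enlarged VOI)
  c2 <- cylinder_spec("C2", 15, 38, activity_kBq = 1200)
  img2 <- make_single_cylinder_image(c2, seed = 21, system = sys)
  voi2 <- threshold_matched_voi(img2, c2$nominal_volume)
  pseudo <- icf(voi_counts(img2, voi2), 1800, 1.2)
  expect_lt(pseudo$value, mean(vals))
})
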