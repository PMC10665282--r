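test_that("voxelization conserves activity and recovers cylinder volumes", {
  # empty layout -> all-zero volume
  lay0 <- phantom_layout(data.frame(id = character(), x = numeric(),
                                    y = numeric()))
  av0 <- voxelize_layout(lay0, list(), voxel_size = 8)
  expect_true(all(av0$conc == 0))

  # C4 alone at 2 mm / supersample 4: activity integral within 0.2%
  c4 <- cylinder_spec("C4", 60, 38, activity_kBq = 19000)
  lay <- phantom_layout(data.frame(id = "C4", x = 0, y = 0))
  av <- voxelize_layout(lay, list(C4 = c4), voxel_size = 2, supersample = 4)
  integral <- sum(av$conc) * 2^3 / 1000
  expect_lt(abs(integral - 19) / 19, 0.002)

  # C1 volume from the occupancy sum within one voxel volume of 1.68 mL
  c1 <- cylinder_spec("C1", 7.5, 38)
  lay1 <- phantom_layout(data.frame(id = "C1", x = 0, y = 0),
                         jaszczak_diameter = 40)
  av1 <- voxelize_layout(lay1, list(C1 = c1), voxel_size = 1,
                         supersample = 8, activities_MBq = c(C1 = 1),
                         padding = 10)
  conc0 <- 1 / c1$nominal_volume  # 1 MBq spread over the nominal volume
  occ_vol <- sum(av1$conc) * 1^3 / 1000 / conc0
  expect_lt(abs(occ_vol - 1.68), 1^3 / 1000)

  # occupancy converges to pi r^2 h: < 0.1% at supersample 8
  c3 <- cylinder_spec("C3", 30, 38)
  av3 <- voxelize_layout(phantom_layout(data.frame(id = "C3", x = 0, y = 0)),
                         list(C3 = c3), voxel_size = 2, supersample = 8,
                         activities_MBq = c(C3 = 1))
  vol3 <- sum(av3$conc) * 2^3 / 1000 * c3$nominal_volume
  expect_lt(abs(vol3 - c3$nominal_volume) / c3$nominal_volume, 0.001)
})

test_that("layout validation rejects overlap and out-of-bounds placements", {
  cyls <- list(A = cylinder_spec("A", 60, 38), B = cylinder_spec("B", 60, 38))
  overlapping <- phantom_layout(data.frame(id = c("A", "B"),
                                           x = c(0, 40), y = c(0, 0)))
  expect_error(validate_phantom_layout(overlapping, cyls), "overlap")
  outside <- phantom_layout(data.frame(id = "A", x = 100, y = 0))
  expect_error(validate_phantom_layout(outside, cyls), "radius")
  expect_error(voxelize_layout(overlapping, cyls, voxel_size = 8), "overlap")
})

test_that("simulated counts follow the forward model", {
  c2 <- cylinder_spec("C2", 15, 38, activity_kBq = 1200)
  sys <- system_model(60, psf_fwhm = 20)

  # zero activity, zero background -> all-zero counts
  av0 <- voxelize_layout(phantom_layout(data.frame(id = "C2", x = 0, y = 0)),
                         list(C2 = c2), voxel_size = 4.42,
                         activities_MBq = c(C2 = 0))
  img0 <- simulate_count_image(av0, sys, i131(), 1800, seed = 1)
  expect_true(all(img0$counts == 0))

  # FWHM 0, no noise -> expected image is exactly the scaled activity image
  av <- voxelize_layout(phantom_layout(data.frame(id = "C2", x = 0, y = 0)),
                        list(C2 = c2), voxel_size = 2, supersample = 4)
  sys0 <- system_model(60, psf_fwhm = 0)
  lam <- simulate_count_image(av, sys0, i131(), 1800, noise = "none")
  scale <- 1800 * true_icf(sys0, i131()) * (2^3 / 1000)
  expect_equal(lam$counts, av$conc * scale, tolerance = 1e-12)

  # count conservation: summed lambda within 0.5% of duration*ICF*A
  # (1 mm grid so that discretisation error is negligible)
  lay_f <- phantom_layout(data.frame(id = "C2", x = 0, y = 0),
                          jaszczak_diameter = 60)
  av_f <- voxelize_layout(lay_f, list(C2 = c2), voxel_size = 1,
                          supersample = 4)
  lam_f <- simulate_count_image(av_f, sys, i131(), 1800, noise = "none")
  closed <- 1800 * 60 * 0.812 * 1.2  # duration * S * p * A
  expect_lt(abs(sum(lam_f$counts) - closed) / closed, 0.005)

  # Monte-Carlo mean of total counts over 100 seeds within 3 sigma (of the
  # mean) of the expected-count image's total on the same grid
  lam20 <- simulate_count_image(av, sys, i131(), 1800, noise = "none")
  totals <- vapply(1:100, function(s)
    sum(simulate_count_image(av, sys, i131(), 1800, seed = s)$counts), 0)
  expect_lt(abs(mean(totals) - sum(lam20$counts)),
            3 * sqrt(sum(lam20$counts) / 100))

  # truth sidecar records the implied true calibration factor
  expect_equal(lam20$truth$icf_true, 60 * 0.812)

  # seeded reproducibility, without clobbering the caller's RNG stream
  set.seed(99); before <- runif(1)
  i1 <- simulate_count_image(av, sys, i131(), 1800, seed = 7)
  i2 <- simulate_count_image(av, sys, i131(), 1800, seed = 7)
  expect_identical(i1$counts, i2$counts)
  set.seed(99)
  expect_identical(runif(1), before)
})

test_that("the Gaussian kernel is normalized", {
  for (sig in c(0.5, 1.7, 4.1)) {
    k <- spectcal:::gaussian_kernel1d(sig)
    expect_lt(abs(sum(k) - 1), 1e-6)
  }
})

test_that("spill-out fraction behaves physically and matches a 3D oracle", {
  c1 <- cylinder_spec("C1", 7.5, 38)
  c4 <- cylinder_spec("C4", 60, 38)
  expect_identical(spillout_fraction(c4, 0), 0)
  s1 <- spillout_fraction(c1, 20)
  s4 <- spillout_fraction(c4, 20)
  expect_gt(s1, s4)  # smaller cylinders lose more to spill-out
  expect_true(s1 >= 0 && s1 < 1 && s4 >= 0 && s4 < 1)
  # monotone non-increasing in diameter at fixed FWHM
  spills <- vapply(c(7.5, 15, 30, 60), function(d)
    spillout_fraction(cylinder_spec("X", d, 38), 20), 0)
  expect_true(all(diff(spills) < 0))
  expect_error(spillout_fraction(c1, 20, voxel_size = 10), "resolution")

  # fine-grid brute-force 3D convolution oracle
  expect_lt(abs(s4 - spillout_3d_oracle(c4, 20)) / s4, 0.01)
  c2 <- cylinder_spec("C2", 15, 38)
  s2 <- spillout_fraction(c2, 20)
  expect_lt(abs(s2 - spillout_3d_oracle(c2, 20)) / s2, 0.01)
})

test_that("placement optimisation finds symmetric optima and beats random layouts", {
  # one cylinder: centred
  c4 <- cylinder_spec("C4", 60, 38)
  lay1 <- optimize_placement(list(C4 = c4), radius_step = 2, angle_step = 10)
  expect_equal(unlist(lay1$positions[, c("x", "y")]), c(x = 0, y = 0),
               tolerance = 1e-9, ignore_attr = TRUE)

  # two identical cylinders: diametrically opposed at equal radius
  two <- list(A = cylinder_spec("A", 30, 38), B = cylinder_spec("B", 30, 38))
  lay2 <- optimize_placement(two, radius_step = 2, angle_step = 10)
  ang <- atan2(lay2$positions$y, lay2$positions$x) * 180 / pi
  expect_lt(abs(abs(((ang[1] - ang[2]) %% 360)) - 180), 10 + 1e-6)
  rad <- sqrt(lay2$positions$x^2 + lay2$positions$y^2)
  expect_equal(rad[1], rad[2], tolerance = 2)

  # four cylinders: optimum no worse than 200 random feasible layouts
  cyls <- paper_cylinders()
  lay4 <- optimize_placement(cyls, radius_step = 2, angle_step = 10)
  obj <- attr(lay4, "objective")
  set.seed(404)
  worse <- 0L
  n_ok <- 0L
  while (n_ok < 200L) {
    pos <- data.frame(id = names(cyls),
                      x = runif(4, -75, 75), y = runif(4, -75, 75))
    cand <- phantom_layout(pos)
    o <- placement_objective(cand, cyls, psf_fwhm = 20)
    if (!is.finite(o)) next
    n_ok <- n_ok + 1L
    if (o < obj - 1e-12) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})
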