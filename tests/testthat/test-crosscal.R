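test_that("emission-probability ratio reproduces the published factor", {
  r <- emission_probability_ratio(ba133(), i131())
  expect_equal(signif(r$ratio, 3), 0.764)
  expect_equal(signif(r$u, 1), 0.005)
  # identical nuclides -> ratio 1; no input uncertainty -> no output one
  same <- emission_probability_ratio(i131(), i131())
  expect_equal(same$ratio, 1)
  a <- radionuclide_spec("A", 1, 100, 0.5)
  b <- radionuclide_spec("B", 1, 100, 0.25)
  expect_equal(emission_probability_ratio(a, b)$u, 0)
})

test_that("the cross-calibration line is unweighted OLS and matches the normal equations", {
  # exact line recovered exactly, zero standard errors
  x <- c(10, 20, 30, 40)
  exact <- data.frame(i131 = x, ba133 = 0.7 * x + 2)
  f <- suppressWarnings(fit_cross_calibration(exact))
  expect_equal(f$slope, 0.7, tolerance = 1e-12)
  expect_equal(f$offset, 2, tolerance = 1e-10)
  expect_lt(f$offset_se, 1e-7)
  expect_lt(f$slope_se, 1e-8)

  # noisy 4-point fixture equals the normal-equation oracle to 1e-10
  set.seed(42)
  for (i in 1:5) {
    xi <- runif(4, 10, 50)
    yi <- 0.76 * xi + rnorm(4, 0, 0.5) + 1
    fit <- fit_cross_calibration(data.frame(i131 = xi, ba133 = yi))
    orc <- ols_oracle(xi, yi)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$offset, orc$offset, tolerance = 1e-10)
    expect_equal(fit$slope_se, orc$slope_se, tolerance = 1e-10)
    expect_equal(fit$offset_se, orc$offset_se, tolerance = 1e-10)
  }

  expect_error(fit_cross_calibration(
    data.frame(i131 = c(10, 10, 10), ba133 = c(7, 8, 9))), "singular")
  expect_error(fit_cross_calibration(exact[1, ]), "at least 2")
})

test_that("cross-calibration conversions map Ba-133 into I-131 units consistently", {
  # identity line
  ident <- suppressWarnings(fit_cross_calibration(
    data.frame(i131 = c(1, 2, 3), ba133 = c(1, 2, 3))))
  expect_equal(apply_cross_calibration(5, ident), 5, tolerance = 1e-10)
  # emission-ratio division
  expect_equal(apply_cross_calibration(38.2, 0.764), 50, tolerance = 1e-3)
  # a tabulated setup line: ba = 2.88 + 0.766 * i131 inverts to
  # (40 - 2.88) / 0.766
  tab <- suppressWarnings(fit_cross_calibration(
    data.frame(i131 = c(10, 20, 40), ba133 = 2.88 + 0.766 * c(10, 20, 40))))
  expect_equal(apply_cross_calibration(40, tab), (40 - 2.88) / 0.766,
               tolerance = 1e-6)
  # both methods agree when the line passes through the origin at slope r
  epr <- emission_probability_ratio(ba133(), i131())
  thr <- suppressWarnings(fit_cross_calibration(
    data.frame(i131 = c(10, 30, 50), ba133 = epr$ratio * c(10, 30, 50))))
  expect_equal(apply_cross_calibration(20, thr),
               apply_cross_calibration(20, epr), tolerance = 1e-6)
})

test_that("relative percentage change is signed and anchored", {
  expect_equal(relative_percent_change(40, 40), 0)
  expect_equal(relative_percent_change(40, 44.8), 12)
  expect_equal(sign(relative_percent_change(40, 36)),
               -sign(relative_percent_change(36, 40)))
  expect_error(relative_percent_change(0, 1), "domain")
})

test_that("the signed-rank test matches exact enumeration and its symmetric null", {
  # mirrored differences: p = 1 up to discreteness
  mir <- wilcoxon_signed_rank(c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5))
  expect_gt(mir$p.value, 0.9)

  # n = 6, all positive: exact two-sided p = 2/2^6
  allpos <- wilcoxon_signed_rank(c(0.3, 1.1, 2.2, 0.7, 1.9, 2.8))
  expect_equal(allpos$p.value, 2 / 64)
  expect_equal(allpos$statistic, 21)

  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0.3, 1.1, 2.2, 0.7, 1.9, 2.8, 0))$n, 6)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")

  # full enumeration oracle for n <= 12
  set.seed(7)
  for (n in c(5, 8, 12)) {
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    res <- wilcoxon_signed_rank(d)
    orc <- wilcoxon_enum_oracle(d)
    expect_equal(res$statistic, orc$statistic)
    expect_equal(res$p.value, orc$p.value, tolerance = 1e-12)
  }
})

test_that("fitted slopes recover the emission-probability and bias ratio on simulated scans", {
  # paired Ba-133 / I-131 acquisitions of the four-cylinder phantom;
  # equal sensitivity, bias ratio 1 -> slope should centre on
  # p_Ba / p_I = 0.764
  ba_set <- ba133_source_set("CMI")
  i_set <- i131_cylinder_set(0.18)
  layout <- phantom_layout(data.frame(id = c("C1", "C2", "C3", "C4"),
                                      x = c(71, 12, -62, -4),
                                      y = c(0, 68, 17, -50)))
  sys <- system_model(60, psf_fwhm = 20)
  av_ba <- voxelize_layout(layout, ba_set, supersample = 2L)
  av_i <- voxelize_layout(layout, i_set, supersample = 2L)
  act_ba <- vapply(ba_set, function(cl) cl$activity_kBq / 1000, 0)
  act_i <- vapply(i_set, function(cl) cl$activity_kBq / 1000, 0)

  one_fit <- function(seed) {
    img_ba <- simulate_count_image(av_ba, sys, ba133(), 1800, seed = seed)
    img_i <- simulate_count_image(av_i, sys, i131(), 1800, seed = seed + 5000)
    pairs <- do.call(rbind, lapply(names(ba_set), function(id) {
      pos <- unlist(layout$positions[layout$positions$id == id, c("x", "y")])
      region <- array(FALSE, dim = dim(img_ba$counts))
      ix <- abs(img_ba$xs - pos[1]) <= ba_set[[id]]$diameter / 2 + 20
      iy <- abs(img_ba$ys - pos[2]) <= ba_set[[id]]$diameter / 2 + 20
      region[ix, iy, ] <- TRUE
      vba <- threshold_matched_voi(img_ba, ba_set[[id]]$active_volume,
                                   region = region)
      vi <- threshold_matched_voi(img_i, i_set[[id]]$nominal_volume,
                                  region = region)
      data.frame(
        i131 = icf(voi_counts(img_i, vi), 1800, act_i[[id]])$value,
        ba133 = icf(voi_counts(img_ba, vba), 1800, act_ba[[id]])$value)
    }))
    fit_cross_calibration(pairs)
  }

  fits <- lapply(1:10, one_fit)
  slopes <- vapply(fits, `[[`, 0, "slope")
  truth <- 0.6205 / 0.812
  # volume-matched thresholding carries a small (<1%) count-dependent
  # selection bias plus the fill-level effect of the underfilled solid
  # sources, so the slope is only anchored loosely here; the tight SE
  # calibration check uses deterministic nominal-geometry masks below
  expect_true(all(abs(slopes - truth) / truth < 0.02))

  # nominal-geometry VOIs on geometry-matched sources: slope unbiased
  ba_nom <- lapply(ba_set, function(cl)
    cylinder_spec(cl$id, cl$diameter, cl$height,
                  activity_kBq = cl$activity_kBq))
  av_nom <- voxelize_layout(layout, ba_nom, supersample = 2L)
  lam <- simulate_count_image(av_i, sys, i131(), 1800, noise = "none")
  masks <- lapply(names(i_set), function(id) {
    pos <- unlist(layout$positions[layout$positions$id == id, c("x", "y")])
    nominal_geometry_voi(lam, i_set[[id]], position = pos)$mask
  })
  names(masks) <- names(i_set)
  fit_nom <- function(seed) {
    img_ba <- simulate_count_image(av_nom, sys, ba133(), 1800, seed = seed)
    img_i <- simulate_count_image(av_i, sys, i131(), 1800, seed = seed + 5000)
    pairs <- do.call(rbind, lapply(names(masks), function(id) data.frame(
      i131 = icf(voi_counts(img_i, masks[[id]]), 1800, act_i[[id]])$value,
      ba133 = icf(voi_counts(img_ba, masks[[id]]), 1800, act_ba[[id]])$value)))
    fit_cross_calibration(pairs)$slope
  }
  slopes_nom <- vapply(101:110, fit_nom, 0)
  expect_lt(abs(mean(slopes_nom) - truth),
            3 * stats::sd(slopes_nom) / sqrt(length(slopes_nom)))
})
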