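test_that("gradient-level masking with an empty mask is a strict identity", {
  ph <- single_bundle_phantom(noise = 300)
  empty <- array(0L, dim(ph$volume$data))
  plain <- sta(ph$volume)
  masked <- sta(ph$volume, mask = empty, mask_mode = "gradient")
  expect_identical(masked$tensor[, , , ], plain$tensor[, , , ])
  expect_identical(masked$metrics$FA, plain$metrics$FA)
})

test_that("an all-one mask suppresses every gradient and tensor entry", {
  ph <- single_bundle_phantom()
  g <- compute_gradients(ph$volume$data, 2)
  gm <- mask_gradients(g, array(1L, dim(ph$volume$data)), dilate_vox = 0)
  expect_true(all(gm == 0))
  S <- compute_structure_tensor(gm, 4)
  expect_true(all(S == 0))
  expect_error(mask_gradients(g, array(1L, c(8, 8, 8))), "shape")
})

test_that("pre-tensor masking zeroes intensities and errors on shape mismatch", {
  ph <- single_bundle_phantom()
  m <- array(0L, dim(ph$volume$data)); m[1:8, , ] <- 1L
  out <- mask_volume_pre_tensor(ph$volume, m)
  expect_true(all(out$data[1:8, , ] == 0))
  expect_identical(out$data[9:64, , ], ph$volume$data[9:64, , ])
  full <- mask_volume_pre_tensor(ph$volume, array(1L, dim(ph$volume$data)))
  expect_true(all(full$data == 0))
  expect_error(mask_volume_pre_tensor(ph$volume, array(0L, c(4, 4, 4))), "shape")
})

test_that("gradient-level masking recovers truth orientation better near vessels", {
  vp <- vessel_phantom()
  res_u <- sta(vp$volume)
  res_m <- sta(vp$volume, mask = vp$mask, mask_mode = "gradient", dilate_vox = 1)
  # supervoxels traversed by vessels, excluding masked/flagged voxels
  affected <- fibrect:::dilate_mask(vp$mask, 3) & !fibrect:::dilate_mask(vp$mask, 1)
  sel_u <- affected & !res_u$eigen$undefined
  sel_m <- affected & !res_m$eigen$undefined
  err_u <- v3_angular_error(res_u$eigen, c(0, 0, 1), sel_u)
  err_m <- v3_angular_error(res_m$eigen, c(0, 0, 1), sel_m)
  expect_lt(median(err_m), median(err_u))
})

test_that("pre-tensor masking injects more vessel-shell gradient energy", {
  # strict inequality must hold for every vessel radius tried
  for (r in c(2, 4, 6)) {
    spec <- phantom_spec(c(48, 48, 48), 12.5,
                         bundles = list(bundle_spec(c(0, 0, 1))),
                         vessels = list(vessel_spec(rbind(c(1, 24, 24), c(48, 24, 24)), r)),
                         noise_sigma = 300, seed = r)
    ph <- generate_fiber_phantom(spec)
    vp <- generate_vessel_phantom(spec, ph$volume)
    g_raw <- compute_gradients(vp$volume$data, 2)
    e_grad <- vessel_shell_energy(mask_gradients(g_raw, vp$mask, 1), vp$mask)
    g_pre <- compute_gradients(mask_volume_pre_tensor(vp$volume, vp$mask)$data, 2)
    e_pre <- vessel_shell_energy(g_pre, vp$mask)
    expect_gt(e_pre, e_grad)
  }
})

test_that("ACC satisfies its algebraic identities", {
  set.seed(6)
  u <- rnorm(45)
  expect_equal(angular_correlation(u, u), 1)
  expect_equal(angular_correlation(u, -u), -1)
  expect_equal(angular_correlation(u, 3.7 * u), 1, tolerance = 1e-12)
  v <- rnorm(45)
  expect_equal(angular_correlation(u, v), angular_correlation(v, u))
  expect_true(abs(angular_correlation(u, v)) <= 1)
  # disjoint support: orthogonal coefficient vectors
  a <- rep(0, 45); a[2:10] <- 1
  b <- rep(0, 45); b[11:20] <- 1
  expect_equal(angular_correlation(a, b), 0)
  # isotropic fODF (zero l >= 1 energy) has undefined angular shape
  iso <- c(1, rep(0, 44))
  expect_true(is.na(angular_correlation(iso, u)))
  expect_error(angular_correlation(u[1:10], v[1:10]), "lmax")
  expect_error(angular_correlation(u, v[1:10]), "length")
})

test_that("paired tests report t, Cohen's d and Wilcoxon consistently", {
  x <- c(1, 2, 3, 4, 5)
  same <- paired_metric_tests(x, x)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$t_p, 1)

  # constant nonzero differences: sd = 0, d is flagged degenerate
  deg <- paired_metric_tests(x + 1, x)
  expect_true(deg$d_degenerate)
  expect_true(is.na(deg$cohens_d))

  # known effect: diffs ~ N(0.5, 1), d should sit near 0.5
  set.seed(17)
  n <- 100
  diffs <- rnorm(n, 0.5, 1)
  pc <- paired_metric_tests(diffs, rep(0, n))
  se_d <- sqrt(1 / n + pc$cohens_d^2 / (2 * n))
  expect_lt(abs(pc$cohens_d - 0.5), 3 * se_d)
  expect_equal(pc$cohens_d, mean(diffs) / sd(diffs))
  expect_lt(pc$wilcoxon_p, 0.01)
  expect_error(paired_metric_tests(1, numeric(0)), "equal length")
})

test_that("ACC equals one without vessels and declines with vessel fraction", {
  # vessel-free control: masked and unmasked pipelines coincide
  ph <- single_bundle_phantom(noise = 300)
  empty <- array(0L, dim(ph$volume$data))
  res_u <- sta(ph$volume)
  res_m <- sta(ph$volume, mask = empty, mask_mode = "gradient")
  fit <- function(r) suppressWarnings(fit_spherical_harmonics(
    aggregate_histograms(r$eigen, 400, 12.5)))
  tab0 <- acc_vs_vessel_fraction(fit(res_u), fit(res_m), empty)
  expect_true(all(abs(tab0$acc - 1) < 1e-6))

  # vessel phantom: stratum-median ACC non-increasing in vessel fraction
  vp <- vessel_phantom()
  vres_u <- sta(vp$volume)
  vres_m <- sta(vp$volume, mask = vp$mask, mask_mode = "gradient")
  tab <- acc_vs_vessel_fraction(fit(vres_u), fit(vres_m), vp$mask)
  expect_true(all(tab$vessel_fraction_pct >= 0))
  sm <- acc_stratum_summary(tab, breaks_pct = c(0, 2, 10))
  expect_true(all(diff(sm$median_acc) <= 1e-12))
  expect_error(
    acc_vs_vessel_fraction(fit(vres_u),
                           suppressWarnings(fit_spherical_harmonics(
                             aggregate_histograms(vres_m$eigen, 800, 12.5))),
                           vp$mask),
    "grids do not match")
})
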