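test_that("histogram counts are conserved and antipodally symmetric", {
  d <- c(16, 16, 16)
  set.seed(3)
  E <- synthetic_eigen_field(random_axes(prod(d)), d)
  h <- aggregate_histograms(E, 200, 12.5)  # one 16^3 supervoxel
  expect_equal(sum(h$counts), 2L * prod(d))
  expect_equal(h$contributing, prod(d))
  # antipodal bins carry equal counts after symmetrization
  bn <- h$binning
  anti <- fibrect:::bin_index(pi - bn$theta, bn$phi + pi, bn)
  expect_identical(h$counts[1, ], h$counts[1, anti])
})

test_that("aligned axes land in the polar bins; flagged voxels are skipped", {
  d <- c(16, 16, 16)
  v <- matrix(rep(c(0, 0, 1), each = prod(d)), ncol = 3)
  E <- synthetic_eigen_field(v, d)
  E$undefined[1:8, 1, 1] <- TRUE
  h <- aggregate_histograms(E, 200, 12.5)
  expect_equal(h$contributing, prod(d) - 8L)
  bn <- h$binning
  polar <- bn$theta < pi / bn$n_theta | bn$theta > pi - pi / bn$n_theta
  expect_equal(sum(h$counts[1, polar]), sum(h$counts))
})

test_that("uniform random axes fill bins in proportion to solid angle", {
  d <- c(40, 40, 40)  # 64000 axes
  set.seed(9)
  E <- synthetic_eigen_field(random_axes(prod(d)), d)
  h <- aggregate_histograms(E, 500, 12.5)
  n <- prod(d)
  p <- h$binning$solid_angle / (4 * pi)
  expected <- 2 * n * p
  se <- sqrt(2 * n * p * (1 - p))
  z <- abs(h$counts[1, ] - expected) / se
  expect_gt(mean(z < 3), 0.985)  # binomial fluctuation allows rare excursions
  expect_true(all(z < 6))
})

test_that("supervoxel partitioning truncates borders with a warning", {
  d <- c(40, 40, 40)
  E <- synthetic_eigen_field(matrix(rep(c(0, 0, 1), each = prod(d)), ncol = 3), d)
  expect_warning(h <- aggregate_histograms(E, 400, 12.5), "truncat|dropped")
  expect_equal(h$sv_dim, c(1L, 1L, 1L))
  expect_equal(h$contributing, 32L^3)
  expect_error(aggregate_histograms(E, 333, 12.5), "whole number")
})

test_that("SH fit of a uniform distribution is isotropic", {
  d <- c(40, 40, 40)
  set.seed(21)
  E <- synthetic_eigen_field(random_axes(prod(d)), d)
  h <- aggregate_histograms(E, 500, 12.5)
  sh <- fit_spherical_harmonics(h)
  cf <- sh$coeffs[1, ]
  expect_true(all(abs(cf[-1]) / abs(cf[1]) < 1e-2))
})

test_that("SH fit of polar mass is strongly peaked at the poles", {
  d <- c(16, 16, 16)
  v <- matrix(rep(c(0, 0, 1), each = prod(d)), ncol = 3)
  E <- synthetic_eigen_field(v, d)
  h <- aggregate_histograms(E, 200, 12.5)
  sh <- suppressWarnings(fit_spherical_harmonics(h))
  pole <- evaluate_fodf(sh$coeffs[1, ], rbind(c(0, 0, 1), c(0, 0, -1)))
  ring <- evaluate_fodf(sh$coeffs[1, ],
                        cbind(cos(seq(0, 2 * pi, length.out = 24)),
                              sin(seq(0, 2 * pi, length.out = 24)), 0))
  expect_gt(min(pole), 5 * max(mean(ring), 0))
})

test_that("fitted fODFs are antipodally symmetric", {
  sh <- fit_spherical_harmonics(
    aggregate_histograms(sta_crossing()$eigen, 800, 12.5))
  set.seed(4)
  dirs <- random_axes(200)
  f1 <- evaluate_fodf(sh$coeffs[1, ], dirs)
  f2 <- evaluate_fodf(sh$coeffs[1, ], -dirs)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("crossing-bundle supervoxel yields two peak pairs near the truth axes", {
  sh <- fit_spherical_harmonics(
    aggregate_histograms(sta_crossing()$eigen, 800, 12.5))
  pk <- fodf_peaks(sh$coeffs[1, ])
  expect_gte(nrow(pk), 2L)
  errs <- apply(pk[1:2, 1:3], 1, function(v)
    min(axial_angle_deg(v, c(0, 0, 1)), axial_angle_deg(v, c(1, 0, 0))))
  expect_true(all(errs < 10))
  # both truth axes are claimed (not twice the same)
  claimed <- apply(pk[1:2, 1:3], 1, function(v)
    which.min(c(axial_angle_deg(v, c(0, 0, 1)), axial_angle_deg(v, c(1, 0, 0)))))
  expect_setequal(claimed, c(1, 2))
})

test_that("GFA obeys its closed forms and scale invariance", {
  expect_equal(gfa(rep(7, 100)), 0)
  for (n in c(2, 5, 100, 724))
    expect_equal(gfa(c(3.2, rep(0, n - 1))), 1, tolerance = 1e-12)
  set.seed(5)
  psi <- abs(rnorm(200))
  expect_equal(gfa(psi), gfa(10 * psi), tolerance = 1e-12)
  expect_equal(gfa(rep(0, 50)), 0)
})

test_that("coherent supervoxels have higher GFA than isotropic ones", {
  sh1 <- suppressWarnings(fit_spherical_harmonics(
    aggregate_histograms(sta_single()$eigen, 800, 12.5)))
  d <- c(40, 40, 40)
  set.seed(31)
  Eiso <- synthetic_eigen_field(random_axes(prod(d)), d)
  sh0 <- fit_spherical_harmonics(aggregate_histograms(Eiso, 500, 12.5))
  expect_gt(min(sh1$gfa), max(sh0$gfa) + 0.3)
})

test_that("halving the supervoxel edge preserves the dominant peak axis", {
  E <- sta_single()$eigen
  sh800 <- suppressWarnings(fit_spherical_harmonics(
    aggregate_histograms(E, 800, 12.5)))
  sh400 <- suppressWarnings(fit_spherical_harmonics(
    aggregate_histograms(E, 400, 12.5)))
  p800 <- fodf_peaks(sh800$coeffs[1, ])[1, 1:3]
  for (s in seq_len(prod(sh400$sv_dim))) {
    p400 <- fodf_peaks(sh400$coeffs[s, ])[1, 1:3]
    expect_lt(axial_angle_deg(p400, p800), 10)
  }
})

test_that("empty and under-determined supervoxels are flagged and ridge-fit", {
  d <- c(16, 16, 16)
  v <- matrix(rep(c(0, 0, 1), each = prod(d)), ncol = 3)
  E <- synthetic_eigen_field(v, d)
  E$undefined[] <- TRUE
  h <- aggregate_histograms(E, 200, 12.5)
  expect_true(h$empty[1])
  sh <- fit_spherical_harmonics(h)
  expect_true(all(is.na(sh$coeffs[1, ])))

  E$undefined[] <- FALSE
  h2 <- aggregate_histograms(E, 200, 12.5)  # delta occupies only 2 bins
  expect_warning(fit_spherical_harmonics(h2), "fewer occupied bins")
})
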