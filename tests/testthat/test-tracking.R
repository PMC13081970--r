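# fODF field + FA map fixture for tracking tests
tracking_fixture <- function() {
  fixture("tracking64", {
    res <- sta_single()
    h <- suppressWarnings(aggregate_histograms(res$eigen, 200, 12.5))
    sh <- suppressWarnings(fit_spherical_harmonics(h))
    fa_sv <- supervoxel_mean_fa(res$metrics$FA, 16)
    list(sh = sh, fa_sv = fa_sv)
  })
}

test_that("tracking configuration bounds are enforced", {
  expect_error(tracking_config(max_turn_deg = 120), "between 0 and 90")
  expect_error(tracking_config(fa_seed_threshold = 1.2), "\\[0, 1\\]")
  expect_error(tracking_config(step_size_um = -1), "positive")
  expect_error(tracking_config(pmf_threshold = 1), "pmf")
})

test_that("seeding counts and placement follow the FA map", {
  cfg <- tracking_config()
  expect_warning(s0 <- seed_streamlines(array(0, c(4, 4, 4)), cfg, 100),
                 "no supervoxel")
  expect_equal(nrow(s0), 0L)

  s1 <- seed_streamlines(array(1, c(4, 4, 4)), cfg, 100)
  expect_equal(nrow(s1), 64L)
  expect_true(all(s1 >= 0 & s1 <= 400))

  # seeds only inside the high-FA bundle territory
  fa <- array(0, c(4, 4, 4)); fa[, , 3:4] <- 0.8
  s2 <- seed_streamlines(fa, cfg, 100)
  expect_true(all(s2[, 3] >= 200))
})

test_that("streamlines honor the turning bound, step length and volume bounds", {
  fx <- tracking_fixture()
  tr <- run_tractography(fx$sh, fx$fa_sv, tracking_config(rng_seed = 42))
  expect_gt(length(tr$streamlines), 0)
  ext <- fx$sh$sv_dim * fx$sh$supervoxel_edge_um
  for (s in tr$streamlines) {
    seg <- diff(s)
    len <- sqrt(rowSums(seg^2))
    expect_true(all(abs(len - tr$step_size_um) < 1e-3 * tr$step_size_um))
    if (nrow(seg) > 1) {
      u <- seg / len
      dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
      turns <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
      expect_true(all(turns <= 30 + 1e-6))
    }
    expect_true(all(s >= 0 & sweep(s, 2, ext) <= 0))
  }
})

test_that("tractography is bitwise reproducible under a fixed seed", {
  fx <- tracking_fixture()
  cfg <- tracking_config(rng_seed = 99)
  t1 <- run_tractography(fx$sh, fx$fa_sv, cfg)
  t2 <- run_tractography(fx$sh, fx$fa_sv, cfg)
  expect_identical(t1$streamlines, t2$streamlines)
  expect_identical(t1$reasons, t2$reasons)
})

test_that("single-bundle streamlines follow the truth axis", {
  fx <- tracking_fixture()
  tr <- run_tractography(fx$sh, fx$fa_sv, tracking_config(rng_seed = 42))
  errs <- vapply(tr$streamlines, function(s) {
    seg <- diff(s); seg <- seg / sqrt(rowSums(seg^2))
    median(acos(pmin(abs(seg[, 3]), 1)) * 180 / pi)
  }, numeric(1))
  expect_gte(mean(errs < 15), 0.9)
})

test_that("low GFA outside the seed supervoxel stops propagation immediately", {
  fx <- tracking_fixture()
  sh <- fx$sh
  g <- sh$gfa
  g[] <- 0.1
  g[2, 2, 2] <- 0.95
  sh$gfa <- g
  set.seed(1)
  # supervoxel-sized steps: the first step must leave the seed supervoxel
  out <- propagate(c(225, 225, 225), sh,
                   tracking_config(step_size_um = 200))
  expect_lte(nrow(out$points), 3L)  # at most 2 steps
  expect_true(all(out$reasons == "low_gfa"))
  expect_error(propagate(c(-10, 0, 0), sh, tracking_config()), "outside")
})

test_that("crossing phantom yields streamline families along both truth axes", {
  res <- sta_crossing()
  h <- suppressWarnings(aggregate_histograms(res$eigen, 200, 12.5))
  sh <- suppressWarnings(fit_spherical_harmonics(h))
  fa_sv <- supervoxel_mean_fa(res$metrics$FA, 16)
  tr <- run_tractography(sh, fa_sv,
                         tracking_config(fa_seed_threshold = 0.3, rng_seed = 8))
  segs <- do.call(rbind, lapply(tr$streamlines, function(s) {
    u <- diff(s); u / sqrt(rowSums(u^2))
  }))
  # axial canonicalization before clustering: flip to positive leading entry
  lead <- apply(abs(segs), 1, which.max)
  flip <- segs[cbind(seq_len(nrow(segs)), lead)] < 0
  segs[flip, ] <- -segs[flip, ]
  km <- stats::kmeans(segs, centers = 2, nstart = 10)
  ctr <- km$centers / sqrt(rowSums(km$centers^2))
  errs <- apply(ctr, 1, function(v)
    min(axial_angle_deg(v, c(0, 0, 1)), axial_angle_deg(v, c(1, 0, 0))))
  expect_true(all(errs < 15))
  claimed <- apply(ctr, 1, function(v)
    which.min(c(axial_angle_deg(v, c(0, 0, 1)), axial_angle_deg(v, c(1, 0, 0)))))
  expect_setequal(claimed, c(1, 2))
})

test_that("TCK export writes a parseable header and the full point stream", {
  fx <- tracking_fixture()
  tr <- run_tractography(fx$sh, fx$fa_sv, tracking_config(rng_seed = 42))
  f <- tempfile(fileext = ".tck")
  write_tck(tr, f)
  raw <- readBin(f, "raw", 1000)
  endpat <- charToRaw("END\n")
  hdr_end <- which(vapply(seq_len(length(raw) - 3L), function(i)
    all(raw[i:(i + 3L)] == endpat), logical(1)))[1] + 3L
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\n")[[1]]
  expect_equal(hdr[1], "mrtrix tracks")
  off_line <- grep("^file:", hdr, value = TRUE)
  off <- as.integer(sub("file: \\. ", "", off_line))
  expect_equal(off, hdr_end)
  con <- file(f, "rb"); seek(con, off)
  vals <- readBin(con, "numeric", size = 4, n = (file.size(f) - off) / 4,
                  endian = "little")
  close(con)
  # first streamline round-trips (mm = um / 1000) up to float32 precision
  p1 <- matrix(vals[seq_len(3 * nrow(tr$streamlines[[1]]))], ncol = 3,
               byrow = TRUE)
  expect_equal(p1, tr$streamlines[[1]] / 1000, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sum(is.nan(vals)), 3 * length(tr$streamlines))
  unlink(f)
})
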