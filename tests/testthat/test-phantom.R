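test_that("phantom generation is deterministic and records truth by construction", {
  spec <- phantom_spec(c(32, 32, 32), 15,
                       bundles = list(bundle_spec(c(0, 0, 1))),
                       noise_sigma = 400, seed = 7)
  a <- generate_fiber_phantom(spec)
  b <- generate_fiber_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)

  # single z-bundle: every in-bundle truth orientation is (0,0,1)
  expect_true(all(a$truth$in_bundle))
  expect_true(all(a$truth$orientation[, , , 1] == 0))
  expect_true(all(a$truth$orientation[, , , 2] == 0))
  expect_true(all(a$truth$orientation[, , , 3] == 1))
  expect_false(any(a$truth$crossing))
})

test_that("overlapping bundles are flagged as crossing with both axes recorded", {
  spec <- phantom_spec(c(32, 32, 32), 15,
                       bundles = list(bundle_spec(c(0, 0, 1)),
                                      bundle_spec(c(1, 0, 0))),
                       seed = 1)
  ph <- generate_fiber_phantom(spec)
  expect_true(all(ph$truth$crossing))
  expect_true(all(is.na(ph$truth$orientation)))
  expect_equal(ph$truth$bundle_axes, list(c(0, 0, 1), c(1, 0, 0)))
  expect_length(ph$truth$bundle_masks, 2L)

  # interleaved slabs do not overlap: both axes present, no crossing
  cr <- crossing_phantom()
  expect_false(any(cr$truth$crossing))
  expect_true(all(cr$truth$in_bundle))
})

test_that("noise-free gradients are perpendicular to the truth axis in bundle interiors", {
  ph <- single_bundle_phantom()
  g <- compute_gradients(ph$volume$data, 2)
  gm <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  sel <- interior_mask(c(64, 64, 64), 10) & gm > 0.1 * max(gm)
  # angle between gradient and the z truth axis
  ang <- acos(pmin(abs(g[, , , 3][sel] / gm[sel]), 1)) * 180 / pi
  expect_true(all(ang >= 85))
})

test_that("phantom spec validation rejects invalid inputs", {
  expect_error(phantom_spec(c(16, 64, 64), 15), "32 voxels")
  expect_error(bundle_spec(c(0, 0, 2)), "unit norm")
  expect_error(phantom_spec(c(64, 64, 64), 15, noise_sigma = -1), "nonnegative")
  expect_error(vessel_spec(rbind(c(1, 1, 1), c(9, 9, 9)), radius_vox = 0),
               "positive")
  spec <- phantom_spec(c(32, 32, 32), 15,
                       vessels = list(vessel_spec(rbind(c(1, 1, 1), c(99, 1, 1)), 2)))
  base <- intensity_volume(array(0, c(32, 32, 32)), 15)
  expect_error(generate_vessel_phantom(spec, base), "outside the volume")
})

test_that("vessel carving matches a brute-force point-in-cylinder oracle", {
  d <- c(32, 32, 32)
  base <- intensity_volume(array(20000, d), 15)

  # empty vessel list: identity volume, all-zero mask
  spec0 <- phantom_spec(d, 15, seed = 1)
  out0 <- generate_vessel_phantom(spec0, base)
  expect_identical(out0$volume$data, base$data)
  expect_true(all(out0$mask == 0L))

  # straight tube along z: compare against an independent closed-form count
  r <- 4.3
  spec <- phantom_spec(d, 15, seed = 1,
                       vessels = list(vessel_spec(rbind(c(16, 16, 1), c(16, 16, 32)), r)))
  out <- generate_vessel_phantom(spec, base)
  grid <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  oracle <- with(grid, (x - 16)^2 + (y - 16)^2 <= r^2)  # z span covers all slices
  expect_identical(as.logical(out$mask), oracle)
  expect_true(all(out$volume$data[out$mask == 1L] == 2000))
  expect_true(all(out$volume$data[out$mask == 0L] == 20000))
})

test_that("per-supervoxel vessel fraction bookkeeping is exact", {
  vp <- vessel_phantom()
  fr <- supervoxel_vessel_fraction(vp$mask, 32L)
  expect_equal(dim(fr), c(2L, 2L, 2L))
  # brute-force recount of one block containing a vessel
  blk <- vp$mask[1:32, 33:64, 33:64]
  expect_identical(fr[1, 2, 2], sum(blk) / length(blk))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("streak injector writes a bright capsule of the requested width", {
  vol <- intensity_volume(array(10000, c(32, 32, 32)), 15)
  out <- inject_streak(vol, c(1, 16, 16), c(32, 16, 16), width_vox = 3,
                       intensity = 60000)
  expect_identical(out$data[16, 16, 16], 60000)
  expect_identical(out$data[16, 16, 17], 60000)  # within radius 1.5
  expect_identical(out$data[16, 16, 20], 10000)  # outside
})
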