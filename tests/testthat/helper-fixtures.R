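# Shared fixtures, memoized across test files (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Single coherent bundle along z, 64^3 at 12.5 um, optionally noisy.
single_bundle_phantom <- function(noise = 0) {
  fixture(paste0("bundle64_", noise), {
    spec <- phantom_spec(c(64, 64, 64), 12.5,
                         bundles = list(bundle_spec(c(0, 0, 1))),
                         noise_sigma = noise, seed = 7)
    generate_fiber_phantom(spec)
  })
}

sta_single <- function(noise = 0) {
  fixture(paste0("sta64_", noise), sta(single_bundle_phantom(noise)$volume))
}

# Pons-like weave: z-bundle and x-bundle in interleaved 8-voxel slabs along y.
crossing_phantom <- function() {
  fixture("crossing64", {
    b1 <- bundle_spec(c(0, 0, 1), thickness_vox = 8, slab_axis = 2)
    b2 <- bundle_spec(c(1, 0, 0), thickness_vox = 8, slab_axis = 2,
                      slab_offset_vox = 8)
    spec <- phantom_spec(c(64, 64, 64), 12.5, bundles = list(b1, b2), seed = 5)
    generate_fiber_phantom(spec)
  })
}

sta_crossing <- function() fixture("sta_crossing", sta(crossing_phantom()$volume))

# z-bundle crossed by dark vessels along x through distinct supervoxels
# (64^3, 32-voxel / 400 um supervoxels).
vessel_phantom <- function() {
  fixture("vessel64", {
    mk <- function(y, z, r) vessel_spec(rbind(c(1, y, z), c(64, y, z)), r)
    spec <- phantom_spec(c(64, 64, 64), 12.5,
                         bundles = list(bundle_spec(c(0, 0, 1))),
                         vessels = list(mk(16, 48, 2), mk(48, 48, 4)),
                         noise_sigma = 300, seed = 11)
    ph <- generate_fiber_phantom(spec)
    vp <- generate_vessel_phantom(spec, ph$volume)
    list(spec = spec, truth = ph$truth, volume = vp$volume, mask = vp$mask)
  })
}

# Axial angle in degrees between unit vectors (sign-free).
axial_angle_deg <- function(u, v) {
  acos(pmin(abs(sum(u * v)), 1)) * 180 / pi
}

# Per-voxel axial angular error of an eigen field against a fixed truth axis,
# over a logical selection.
v3_angular_error <- function(E, axis, sel) {
  dp <- E$v3[, , , 1] * axis[1] + E$v3[, , , 2] * axis[2] +
    E$v3[, , , 3] * axis[3]
  acos(pmin(abs(dp[sel]), 1)) * 180 / pi
}

# Interior selection mask (margin voxels off each face).
interior_mask <- function(d, margin) {
  m <- array(FALSE, dim = d)
  m[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin),
    (margin + 1):(d[3] - margin)] <- TRUE
  m
}

# Synthetic eigen field with prescribed v3 vectors (for histogram tests).
synthetic_eigen_field <- function(v3_matrix, d) {
  v <- array(0, dim = c(d, 3L))
  for (a in 1:3) v[, , , a] <- array(v3_matrix[, a], dim = d)
  structure(list(lambda = array(1, dim = c(d, 3L)), v3 = v,
                 undefined = array(FALSE, dim = d)),
            class = "eigen_field")
}

# Random unit axes (rows), fixed seed handled by caller.
random_axes <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
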