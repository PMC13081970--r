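#' Fiber bundle description for phantom generation
#'
#' A bundle is a territory of the volume filled with bright striations
#' perpendicular to a single axis — the synthetic analogue of a coherent
#' fascicle. Intensity inside the territory is modulated sinusoidally along
#' two orthogonal directions perpendicular to `axis` (period `spacing_vox`),
#' so the noise-free image gradient everywhere in the bundle interior lies in
#' the plane perpendicular to the fiber axis, as it does for real striated
#' fascicles. Territories are full-volume by default, or periodic slabs
#' (useful for interdigitated, pons-like weaves of two orthogonal bundles).
#'
#' @param axis Unit 3-vector, the fiber axis (axial: sign-free).
#' @param spacing_vox Striation period in voxels.
#' @param thickness_vox Slab thickness in voxels; `Inf` = whole volume.
#' @param amplitude Peak-to-trough intensity modulation (16-bit scale).
#' @param slab_axis Axis (1, 2 or 3) along which slabs repeat; only used when
#'   `thickness_vox` is finite.
#' @param slab_period_vox Slab repeat period; default `2 * thickness_vox`.
#' @param slab_offset_vox Offset of the first slab.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(axis, spacing_vox = 8, thickness_vox = Inf,
                        amplitude = 20000, slab_axis = 3L,
                        slab_period_vox = NULL, slab_offset_vox = 0L) {
  axis <- as.numeric(axis)
  if (length(axis) != 3L || !all(is.finite(axis)))
    stop("bundle axis must be a finite 3-vector")
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6)
    stop("bundle axis must have unit norm (got ", signif(nrm, 6), ")")
  if (spacing_vox <= 0 || amplitude <= 0) stop("spacing and amplitude must be positive")
  if (is.null(slab_period_vox)) slab_period_vox <- 2 * thickness_vox
  structure(list(axis = axis / nrm, spacing_vox = spacing_vox,
                 thickness_vox = thickness_vox, amplitude = amplitude,
                 slab_axis = as.integer(slab_axis),
                 slab_period_vox = slab_period_vox,
                 slab_offset_vox = slab_offset_vox),
            class = "bundle_spec")
}

#' Vessel description for phantom generation
#'
#' Vessels are dark tubes: all voxels whose centers lie within `radius_vox`
#' of the centerline polyline are set to a low intensity, emulating the
#' tubular low-intensity voids that vasculature produces in label-free
#' phase-contrast volumes.
#'
#' @param centerline k x 3 matrix of voxel coordinates (1-based, may be
#'   fractional) defining a polyline; a single row plus `axis`/`length` is
#'   not supported — give at least two points.
#' @param radius_vox Positive tube radius in voxels.
#' @param intensity Intensity assigned to vessel voxels (dark; default 2000).
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(centerline, radius_vox, intensity = 2000) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("centerline must be a k x 3 matrix with k >= 2")
  if (!is.numeric(radius_vox) || radius_vox <= 0)
    stop("vessel radius must be positive")
  structure(list(centerline = centerline, radius_vox = radius_vox,
                 intensity = intensity),
            class = "vessel_spec")
}

#' Phantom specification
#'
#' Collects everything needed to generate a synthetic volume with known fiber
#' orientations and vessel geometry: grid shape, voxel size, bundles, vessels,
#' noise level and RNG seed. Intensities follow the conventions of label-free
#' phase-contrast data: fibers bright, vessels dark, background mid-gray, on
#' a 16-bit unsigned range.
#'
#' @param shape Integer 3-vector of voxel counts (each >= 32).
#' @param voxel_size_um Positive voxel size (um).
#' @param bundles List of [bundle_spec()] objects.
#' @param vessels List of [vessel_spec()] objects.
#' @param noise_sigma Nonnegative additive Gaussian noise standard deviation.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @param background Background intensity (default 20000).
#' @param range Dynamic range for clipping, default `c(0, 65535)`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, voxel_size_um, bundles = list(),
                         vessels = list(), noise_sigma = 0, seed = 1L,
                         background = 20000, range = c(0, 65535)) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 32L)) stop("phantom shape must be at least 32 voxels per axis")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (!all(vapply(bundles, inherits, logical(1), "bundle_spec")))
    stop("bundles must be a list of bundle_spec objects")
  if (!all(vapply(vessels, inherits, logical(1), "vessel_spec")))
    stop("vessels must be a list of vessel_spec objects")
  structure(list(shape = shape, voxel_size_um = as.numeric(voxel_size_um),
                 bundles = bundles, vessels = vessels,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 background = background, range = range),
            class = "phantom_spec")
}

# Deterministic orthonormal complement of a unit axis.
perp_basis <- function(axis) {
  e <- c(0, 0, 0)
  e[which.min(abs(axis))] <- 1
  p1 <- c(axis[2] * e[3] - axis[3] * e[2],
          axis[3] * e[1] - axis[1] * e[3],
          axis[1] * e[2] - axis[2] * e[1])
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(axis[2] * p1[3] - axis[3] * p1[2],
          axis[3] * p1[1] - axis[1] * p1[3],
          axis[1] * p1[2] - axis[2] * p1[1])
  list(p1 = p1, p2 = p2)
}

bundle_territory <- function(b, shape) {
  if (!is.finite(b$thickness_vox)) return(array(TRUE, dim = shape))
  coords <- switch(b$slab_axis,
                   slice.index(array(0L, shape), 1L),
                   slice.index(array(0L, shape), 2L),
                   slice.index(array(0L, shape), 3L))
  phase <- (coords - 1L - b$slab_offset_vox) %% b$slab_period_vox
  array(phase < b$thickness_vox, dim = shape)
}

#' Generate a synthetic fiber phantom with ground truth
#'
#' Builds the noise-free striation pattern for each bundle within its
#' territory, sums overlapping bundles, clips to the dynamic range, and adds
#' Gaussian noise. The returned truth records, per voxel, the axis of the
#' covering bundle (`NA` outside all bundles), a crossing flag where two or
#' more bundles with different axes overlap, and the per-bundle territory
#' masks and axes for downstream oracles.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (an [intensity_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_fiber_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  arr <- array(spec$background, dim = d)
  n_cover <- array(0L, dim = d)
  orientation <- array(NA_real_, dim = c(d, 3L))
  masks <- list(); axes <- list()

  xi <- slice.index(array(0L, d), 1L)
  yi <- slice.index(array(0L, d), 2L)
  zi <- slice.index(array(0L, d), 3L)

  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    terr <- bundle_territory(b, d)
    pb <- perp_basis(b$axis)
    u1 <- xi * pb$p1[1] + yi * pb$p1[2] + zi * pb$p1[3]
    u2 <- xi * pb$p2[1] + yi * pb$p2[2] + zi * pb$p2[3]
    stri <- b$amplitude / 2 +
      (b$amplitude / 4) * (cos(2 * pi * u1 / b$spacing_vox) +
                           cos(2 * pi * u2 / b$spacing_vox))
    arr[terr] <- arr[terr] + stri[terr]
    n_cover <- n_cover + terr
    for (a in 1:3) {
      comp <- orientation[, , , a]
      comp[terr] <- b$axis[a]
      orientation[, , , a] <- comp
    }
    masks[[bi]] <- terr
    axes[[bi]] <- b$axis
  }
  crossing <- n_cover > 1L
  if (any(crossing)) {  # ambiguous voxel-level axis; both axes stay in `axes`
    for (a in 1:3) {
      comp <- orientation[, , , a]
      comp[crossing] <- NA_real_
      orientation[, , , a] <- comp
    }
  }
  arr <- pmin(pmax(arr, spec$range[1]), spec$range[2])
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    arr <- arr + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
  }
  truth <- structure(list(orientation = orientation,
                          in_bundle = n_cover > 0L,
                          crossing = crossing,
                          bundle_masks = masks, bundle_axes = axes),
                     class = "phantom_truth")
  list(volume = intensity_volume(arr, spec$voxel_size_um), truth = truth)
}

# Rasterize a polyline capsule: logical mask of voxels whose centers lie
# within `radius` of any centerline segment. Works per segment on a bounding
# box expanded by the radius, so large volumes stay cheap.
rasterize_tube <- function(shape, centerline, radius) {
  mask <- array(FALSE, dim = shape)
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]; b <- centerline[s + 1L, ]
    lo <- pmax(floor(pmin(a, b) - radius), 1)
    hi <- pmin(ceiling(pmax(a, b) + radius), shape)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- expand.grid(x = ix, y = iy, z = iz)
    ab <- b - a
    ab2 <- sum(ab^2)
    px <- g$x - a[1]; py <- g$y - a[2]; pz <- g$z - a[3]
    t <- if (ab2 > 0) pmin(pmax((px * ab[1] + py * ab[2] + pz * ab[3]) / ab2, 0), 1)
         else rep(0, nrow(g))
    dx <- px - t * ab[1]; dy <- py - t * ab[2]; dz <- pz - t * ab[3]
    inside <- (dx^2 + dy^2 + dz^2) <= radius^2
    if (any(inside)) {
      idx <- cbind(g$x[inside], g$y[inside], g$z[inside])
      mask[idx] <- TRUE
    }
  }
  mask
}

#' Carve dark tubular vessels into a volume
#'
#' Voxels within each vessel's radius of its centerline are set to the
#' vessel intensity; the returned binary mask marks exactly those voxels.
#'
#' @param spec A [phantom_spec()] whose `vessels` list is used.
#' @param base An [intensity_volume()] to carve into (typically the fiber
#'   phantom output).
#' @param max_fraction Optional cap on the overall vessel volume fraction;
#'   exceeding it triggers a warning reporting the achieved fraction.
#' @return List with `volume` (carved copy) and `mask` (0/1 integer array).
#' @export
generate_vessel_phantom <- function(spec, base, max_fraction = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), is_intensity_volume(base))
  d <- dim(base$data)
  mask <- array(FALSE, dim = d)
  for (v in spec$vessels) {
    if (any(v$centerline < 1) || any(sweep(v$centerline, 2, d) > 0))
      stop("vessel centerline lies outside the volume")
    mask <- mask | rasterize_tube(d, v$centerline, v$radius_vox)
  }
  arr <- base$data
  for (v in spec$vessels) {
    m <- rasterize_tube(d, v$centerline, v$radius_vox)
    arr[m] <- v$intensity
  }
  frac <- mean(mask)
  if (!is.null(max_fraction) && frac > max_fraction)
    warning(sprintf("achieved vessel fraction %.4f exceeds cap %.4f",
                    frac, max_fraction))
  list(volume = intensity_volume(arr, base$voxel_size_um),
       mask = array(as.integer(mask), dim = d))
}

#' Inject a bright streak artifact
#'
#' Phase-contrast reconstructions can contain bright linear streaks near
#' sharp density transitions; these introduce artificial linear features that
#' bias gradient-based orientation estimation. This injector writes a single
#' bright capsule (line segment of given width) into a copy of the volume,
#' for artifact-robustness experiments.
#'
#' @param vol An [intensity_volume()].
#' @param from,to Endpoints (voxel coordinates, length 3).
#' @param width_vox Full width of the streak in voxels.
#' @param intensity Streak intensity (default 60000).
#' @return A new [intensity_volume()].
#' @export
inject_streak <- function(vol, from, to, width_vox = 2, intensity = 60000) {
  stopifnot(is_intensity_volume(vol))
  m <- rasterize_tube(dim(vol$data), rbind(from, to), width_vox / 2)
  arr <- vol$data
  arr[m] <- intensity
  intensity_volume(arr, vol$voxel_size_um)
}

#' Per-supervoxel vessel volume fraction
#'
#' Exact bookkeeping: fraction = vessel voxels / total voxels within each
#' supervoxel block. Partial border supervoxels are truncated (dropped), in
#' step with [aggregate_histograms()].
#'
#' @param mask 0/1 vessel mask array.
#' @param edge_vox Supervoxel edge length in fine voxels.
#' @return 3D array of fractions on the supervoxel grid.
#' @export
supervoxel_vessel_fraction <- function(mask, edge_vox) {
  d <- dim(mask)
  edge_vox <- as.integer(edge_vox)
  nsv <- d %/% edge_vox
  if (any(nsv < 1L)) stop("supervoxel edge larger than the volume")
  out <- array(0, dim = nsv)
  for (k in seq_len(nsv[3])) for (j in seq_len(nsv[2])) for (i in seq_len(nsv[1])) {
    blk <- mask[((i - 1L) * edge_vox + 1L):(i * edge_vox),
                ((j - 1L) * edge_vox + 1L):(j * edge_vox),
                ((k - 1L) * edge_vox + 1L):(k * edge_vox)]
    out[i, j, k] <- sum(blk) / length(blk)
  }
  out
}
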