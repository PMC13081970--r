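## Supervoxel fODFs: spherical histograms of v3 orientations, real even-order
## spherical-harmonic fits, GFA, and peak extraction.

#' Equal-angle spherical binning
#'
#' Partition of the unit sphere into an equal-angle grid in elevation
#' `theta in (0, pi)` and azimuth `phi in (0, 2*pi)`. Equal-angle bins have
#' unequal solid angles (polar bins are small), so per-bin solid angles are
#' carried along and used to convert counts into densities before fitting.
#'
#' @param n_theta,n_phi Bin counts (defaults 16 x 32).
#' @return List with bin centers (`theta`, `phi`), unit direction vectors at
#'   the centers (`dirs`, nbins x 3), per-bin solid angles (`solid_angle`),
#'   and the grid dimensions.
#' @export
sphere_binning <- function(n_theta = 16L, n_phi = 32L) {
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  stopifnot(n_theta >= 2L, n_phi >= 4L)
  te <- seq(0, pi, length.out = n_theta + 1L)
  pe <- seq(0, 2 * pi, length.out = n_phi + 1L)
  tc <- (te[-1] + te[-length(te)]) / 2
  pc <- (pe[-1] + pe[-length(pe)]) / 2
  grid <- expand.grid(ip = seq_len(n_phi), it = seq_len(n_theta))
  theta <- tc[grid$it]; phi <- pc[grid$ip]
  sa <- (cos(te[grid$it]) - cos(te[grid$it + 1L])) * (2 * pi / n_phi)
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  list(theta = theta, phi = phi, dirs = dirs, solid_angle = sa,
       n_theta = n_theta, n_phi = n_phi, theta_edges = te, phi_edges = pe)
}

bin_index <- function(theta, phi, binning) {
  it <- pmin(pmax(floor(theta / pi * binning$n_theta), 0), binning$n_theta - 1L)
  ip <- pmin(pmax(floor((phi %% (2 * pi)) / (2 * pi) * binning$n_phi), 0),
             binning$n_phi - 1L)
  as.integer(it * binning$n_phi + ip + 1L)
}

#' Real spherical-harmonic basis
#'
#' Orthonormal real spherical harmonics evaluated at `(theta, phi)`. For the
#' axial orientation data handled here only even orders are used (the
#' symmetrized input forces odd terms to zero); `lmax = 8` even-only gives 45
#' coefficients. Column order: l ascending, m from -l to l within each l.
#'
#' @param theta,phi Numeric vectors (radians), equal length.
#' @param lmax Maximum order (default 8).
#' @param even_only Keep even l only (default TRUE).
#' @return Matrix `length(theta) x n_coef`.
#' @export
sh_basis <- function(theta, phi, lmax = 8L, even_only = TRUE) {
  stopifnot(length(theta) == length(phi))
  ls <- if (even_only) seq(0L, lmax, by = 2L) else 0L:lmax
  n <- length(theta)
  x <- cos(theta)
  cols <- list()
  for (l in ls) {
    P <- pracma::legendre(l, x)            # (l+1) x n, rows m = 0..l, CS phase
    if (l == 0L) P <- matrix(P, nrow = 1L)
    for (m in (-l):l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pm <- P[am + 1L, ]
      y <- if (m == 0) N * Pm
           else if (m > 0) sqrt(2) * N * Pm * cos(m * phi)
           else sqrt(2) * N * Pm * sin(am * phi)
      cols[[length(cols) + 1L]] <- y
    }
  }
  B <- do.call(cbind, cols)
  attr(B, "l_degrees") <- unlist(lapply(ls, function(l) rep(l, 2L * l + 1L)))
  B
}

n_sh_coef <- function(lmax = 8L, even_only = TRUE) {
  ls <- if (even_only) seq(0L, lmax, by = 2L) else 0L:lmax
  sum(2L * ls + 1L)
}

#' Aggregate fiber orientations into supervoxel spherical histograms
#'
#' Partitions the fine-voxel v3 field into cubic supervoxels (edge given in
#' micrometers, e.g. 800 to match a dMRI voxel) and bins the orientations of
#' all non-flagged voxels into a spherical histogram per supervoxel. Each
#' orientation contributes one count to its bin and one to the antipodal bin
#' (axial symmetrization), so histogram totals equal twice the contributing
#' voxel count. Partial border supervoxels are truncated with a warning.
#'
#' @param E An `eigen_field` from [eigendecompose()] / [sta()].
#' @param supervoxel_edge_um Supervoxel edge length (um); must be a whole
#'   multiple of the voxel size.
#' @param voxel_size_um Fine voxel size (um).
#' @param binning A [sphere_binning()] (default 16 x 32).
#' @return Object of class `spherical_histogram_field`: counts matrix
#'   (n_supervoxels x n_bins), supervoxel grid dims `sv_dim`, per-supervoxel
#'   contributing-voxel counts, `empty` flags, the binning, and sizes.
#' @export
aggregate_histograms <- function(E, supervoxel_edge_um, voxel_size_um,
                                 binning = sphere_binning()) {
  stopifnot(inherits(E, "eigen_field"))
  edge <- supervoxel_edge_um / voxel_size_um
  if (abs(edge - round(edge)) > 1e-8)
    stop("supervoxel edge (", supervoxel_edge_um,
         " um) is not a whole number of fine voxels")
  edge <- as.integer(round(edge))
  d <- dim(E$undefined)
  nsv <- d %/% edge
  if (any(nsv < 1L)) stop("supervoxel edge larger than the volume")
  if (any(d %% edge != 0L))
    warning("volume extent is not a multiple of the supervoxel edge; ",
            "partial border supervoxels are dropped")

  keep <- !E$undefined
  # drop voxels beyond the truncated supervoxel grid
  xi <- slice.index(keep, 1L); yi <- slice.index(keep, 2L); zi <- slice.index(keep, 3L)
  inside <- xi <= nsv[1] * edge & yi <= nsv[2] * edge & zi <= nsv[3] * edge
  sel <- which(keep & inside)
  n_bins <- length(binning$solid_angle)
  n_sv <- prod(nsv)
  counts <- matrix(0L, nrow = n_sv, ncol = n_bins)
  contributing <- integer(n_sv)
  if (length(sel)) {
    v <- matrix(c(E$v3[, , , 1][sel], E$v3[, , , 2][sel], E$v3[, , , 3][sel]),
                ncol = 3L)
    sv <- ((xi[sel] - 1L) %/% edge) +
          ((yi[sel] - 1L) %/% edge) * nsv[1] +
          ((zi[sel] - 1L) %/% edge) * nsv[1] * nsv[2] + 1L
    theta <- acos(pmin(pmax(v[, 3], -1), 1))
    phi <- atan2(v[, 2], v[, 1]) %% (2 * pi)
    b1 <- bin_index(theta, phi, binning)
    b2 <- bin_index(pi - theta, phi + pi, binning)  # antipode
    tab <- tabulate((sv - 1L) * n_bins + b1, nbins = n_sv * n_bins) +
           tabulate((sv - 1L) * n_bins + b2, nbins = n_sv * n_bins)
    counts <- matrix(tab, nrow = n_sv, ncol = n_bins, byrow = TRUE)
    contributing <- tabulate(sv, nbins = n_sv)
  }
  structure(list(counts = counts, sv_dim = nsv, contributing = contributing,
                 empty = contributing == 0L, binning = binning,
                 supervoxel_edge_um = supervoxel_edge_um,
                 voxel_size_um = voxel_size_um, edge_vox = edge),
            class = "spherical_histogram_field")
}

#' @export
print.spherical_histogram_field <- function(x, ...) {
  cat(sprintf("<spherical_histogram_field> %s supervoxels (%g um), %d bins, %d empty\n",
              paste(x$sv_dim, collapse = "x"), x$supervoxel_edge_um,
              ncol(x$counts), sum(x$empty)))
  invisible(x)
}

#' Fit spherical harmonics to supervoxel histograms
#'
#' Converts each histogram to a solid-angle density (count / bin solid angle
#' / total count) at the bin centers and fits the real even-order SH basis by
#' solid-angle-weighted linear least squares with a small ridge for
#' stability. Supervoxels with fewer occupied bins than coefficients are fit
#' with a stronger ridge (with a warning). Coefficients are scaled so the
#' fitted fODF integrates to 1 over the sphere; GFA is computed from the
#' fitted fODF sampled on a fixed set of `n_gfa_dirs` approximately uniform
#' directions (Fibonacci sphere), clipped at zero.
#'
#' @param h A `spherical_histogram_field`.
#' @param lmax Maximum SH order (default 8, even orders only).
#' @param ridge Ridge parameter (default 1e-8); `ridge_degenerate` is used
#'   for under-determined supervoxels (default 1e-3).
#' @param ridge_degenerate See `ridge`.
#' @param n_gfa_dirs Number of sphere samples for GFA (default 200, >= 100).
#' @return Object of class `sh_field`: `coeffs` (n_supervoxels x n_coef,
#'   NA rows for empty supervoxels), `gfa` (3D array on the supervoxel
#'   grid), `sv_dim`, basis metadata and the histogram bookkeeping.
#' @export
fit_spherical_harmonics <- function(h, lmax = 8L, ridge = 1e-8,
                                    ridge_degenerate = 1e-3,
                                    n_gfa_dirs = 200L) {
  stopifnot(inherits(h, "spherical_histogram_field"), n_gfa_dirs >= 100L)
  B <- sh_basis(h$binning$theta, h$binning$phi, lmax, even_only = TRUE)
  nc <- ncol(B)
  w <- h$binning$solid_angle
  BtW <- t(B * w)
  A <- BtW %*% B
  n_sv <- nrow(h$counts)
  coeffs <- matrix(NA_real_, n_sv, nc)
  occ <- rowSums(h$counts > 0L)
  degen <- !h$empty & occ < nc
  if (any(degen))
    warning(sum(degen), " supervoxel(s) have fewer occupied bins than SH ",
            "coefficients; fitted with ridge ", ridge_degenerate)
  fill <- function(rows, lam) {
    if (!length(rows)) return()
    Y <- t(h$counts[rows, , drop = FALSE] / h$contributing[rows]) / w / 2
    sol <- solve(A + diag(lam, nc), BtW %*% Y)
    coeffs[rows, ] <<- t(sol)
  }
  fill(which(!h$empty & !degen), ridge)
  fill(which(degen), ridge_degenerate)

  # normalize: integral over the sphere = c00 * sqrt(4*pi) = 1
  c00 <- coeffs[, 1]
  ok <- !is.na(c00) & c00 > 0
  coeffs[ok, ] <- coeffs[ok, , drop = FALSE] / (c00[ok] * sqrt(4 * pi))

  gdirs <- fibonacci_sphere(n_gfa_dirs)
  Bg <- sh_basis(acos(pmin(pmax(gdirs[, 3], -1), 1)),
                 atan2(gdirs[, 2], gdirs[, 1]), lmax, even_only = TRUE)
  gfa_v <- rep(NA_real_, n_sv)
  if (any(ok)) {
    vals <- coeffs[ok, , drop = FALSE] %*% t(Bg)
    vals[vals < 0] <- 0
    gfa_v[ok] <- apply(vals, 1L, gfa)
  }
  structure(list(coeffs = coeffs, gfa = array(gfa_v, dim = h$sv_dim),
                 sv_dim = h$sv_dim, lmax = as.integer(lmax), even_only = TRUE,
                 basis = "real, orthonormal, even orders, m = -l..l",
                 supervoxel_edge_um = h$supervoxel_edge_um,
                 voxel_size_um = h$voxel_size_um, edge_vox = h$edge_vox,
                 contributing = h$contributing, empty = h$empty),
            class = "sh_field")
}

#' @export
print.sh_field <- function(x, ...) {
  cat(sprintf("<sh_field> %s supervoxels (%g um), lmax %d (%d coef), median GFA %.3f\n",
              paste(x$sv_dim, collapse = "x"), x$supervoxel_edge_um, x$lmax,
              ncol(x$coeffs), stats::median(x$gfa, na.rm = TRUE)))
  invisible(x)
}

#' Evaluate a fitted fODF
#'
#' @param coeffs Coefficient vector (length `n_sh_coef(lmax)`).
#' @param dirs n x 3 matrix of unit directions.
#' @param lmax,even_only Basis parameters matching the fit.
#' @param clip Clip negative lobes to zero (used when sampling for
#'   tractography; keep `FALSE` for coefficient-level analyses).
#' @return Numeric vector of fODF amplitudes.
#' @export
evaluate_fodf <- function(coeffs, dirs, lmax = 8L, even_only = TRUE,
                          clip = FALSE) {
  B <- sh_basis(acos(pmin(pmax(dirs[, 3], -1), 1)),
                atan2(dirs[, 2], dirs[, 1]), lmax, even_only)
  f <- as.numeric(B %*% coeffs)
  if (clip) f[f < 0] <- 0
  f
}

#' Generalized fractional anisotropy of sampled fODF amplitudes
#'
#' `GFA = std(psi) / rms(psi) = sqrt(n * sum((psi_i - mean)^2) /
#' ((n - 1) * sum(psi_i^2)))` over `n` sphere samples. Zero for a constant
#' fODF, exactly one when a single sample is nonzero, invariant to positive
#' scaling. All-zero samples return 0 by definition.
#'
#' @param psi Numeric vector of fODF amplitudes (length >= 2).
#' @return GFA scalar in \[0, 1\].
#' @export
gfa <- function(psi) {
  n <- length(psi)
  stopifnot(n >= 2L)
  ss <- sum(psi^2)
  if (ss == 0) return(0)
  sqrt(n * sum((psi - mean(psi))^2) / ((n - 1) * ss))
}

#' Approximately uniform sphere direction sets
#'
#' `fibonacci_sphere(n)` is the golden-spiral point set on the full sphere;
#' `symmetric_sphere_set(n)` is an antipodally symmetric set built from
#' `n / 2` spiral points plus their antipodes (used for fODF sampling in
#' tractography and for peak finding).
#'
#' @param n Number of points (even for the symmetric set).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @rdname fibonacci_sphere
#' @export
symmetric_sphere_set <- function(n = 724L) {
  stopifnot(n %% 2L == 0L)
  half <- fibonacci_sphere(n %/% 2L)
  rbind(half, -half)
}

#' Find fODF peaks by dense grid search
#'
#' Evaluates the (clipped) fODF on a dense antipodally symmetric grid and
#' returns local maxima: directions whose amplitude is not exceeded within a
#' `neighborhood_deg` cone, merged over antipodes and separated by at least
#' `min_separation_deg` (axial angle). Peaks below `rel_threshold` times the
#' global maximum are dropped.
#'
#' @param coeffs fODF coefficient vector.
#' @param lmax,even_only Basis parameters.
#' @param grid_n Grid size (default 1442).
#' @param neighborhood_deg Local-maximum neighborhood (default 12).
#' @param min_separation_deg Minimum axial separation between peaks.
#' @param rel_threshold Relative amplitude cutoff (default 0.25).
#' @return Matrix with columns `x, y, z, amplitude`, one row per peak,
#'   strongest first; zero rows if the fODF is nonpositive everywhere.
#' @export
fodf_peaks <- function(coeffs, lmax = 8L, even_only = TRUE, grid_n = 1442L,
                       neighborhood_deg = 12, min_separation_deg = 20,
                       rel_threshold = 0.25) {
  dirs <- symmetric_sphere_set(grid_n)
  f <- evaluate_fodf(coeffs, dirs, lmax, even_only, clip = TRUE)
  if (max(f) <= 0) return(matrix(numeric(0), ncol = 4L,
                                 dimnames = list(NULL, c("x", "y", "z", "amplitude"))))
  cosnb <- cos(neighborhood_deg * pi / 180)
  D <- abs(dirs %*% t(dirs))  # axial angular proximity
  is_max <- vapply(seq_len(nrow(dirs)), function(i) {
    nb <- which(D[i, ] >= cosnb)
    f[i] >= max(f[nb])
  }, logical(1))
  cand <- which(is_max & f >= rel_threshold * max(f))
  cand <- cand[order(f[cand], decreasing = TRUE)]
  cossep <- cos(min_separation_deg * pi / 180)
  picked <- integer(0)
  for (i in cand) {
    if (!length(picked) || all(abs(dirs[picked, , drop = FALSE] %*% dirs[i, ]) < cossep))
      picked <- c(picked, i)
  }
  cbind(dirs[picked, , drop = FALSE], amplitude = f[picked],
        deparse.level = 0) -> out
  colnames(out) <- c("x", "y", "z", "amplitude")
  out
}

#' Per-supervoxel peak table
#'
#' Text-exportable summary of fODF peaks for every non-empty supervoxel.
#'
#' @param sh An `sh_field`.
#' @param ... Passed to [fodf_peaks()].
#' @return data.frame with supervoxel indices, peak rank, axis and amplitude.
#' @export
peak_table <- function(sh, ...) {
  stopifnot(inherits(sh, "sh_field"))
  nsv <- sh$sv_dim
  rows <- list()
  for (s in which(!sh$empty)) {
    pk <- fodf_peaks(sh$coeffs[s, ], lmax = sh$lmax, ...)
    if (!nrow(pk)) next
    idx <- arrayInd(s, nsv)
    rows[[length(rows) + 1L]] <- data.frame(
      sv_x = idx[1], sv_y = idx[2], sv_z = idx[3],
      rank = seq_len(nrow(pk)),
      x = pk[, "x"], y = pk[, "y"], z = pk[, "z"],
      amplitude = pk[, "amplitude"])
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
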