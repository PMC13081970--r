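## Structure tensor analysis: smoothed gradients, tensor aggregation,
## eigendecomposition and scalar shape/anisotropy maps.

boundary_mode_code <- function(mode) {
  switch(mode, reflect = 0L, nearest = 1L, constant = 2L,
         stop("unknown boundary mode ", mode))
}

#' Gaussian and derivative-of-Gaussian kernels
#'
#' 1D kernels truncated at `truncate` standard deviations. The smoothing
#' kernel is normalized to unit sum; the derivative kernel is normalized so
#' that correlation with a discrete unit ramp yields exactly 1, making the
#' gradient of a linear intensity ramp exact in the interior.
#'
#' @param sigma Standard deviation in voxels (> 0).
#' @param truncate Kernel cutoff in standard deviations (default 4).
#' @return Numeric kernel vector of odd length `2*ceiling(truncate*sigma)+1`.
#' @export
gaussian_kernel <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0)
  r <- ceiling(truncate * sigma)
  t <- (-r):r
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussian_kernel
#' @export
gaussian_deriv_kernel <- function(sigma, truncate = 4) {
  r <- ceiling(truncate * sigma)
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- t * g / sigma^2
  k / sum(t * k)  # exact unit response to a ramp
}

#' Support radius of the structure-tensor pipeline
#'
#' The gradient stage has support `ceiling(truncate * sigma)` and the tensor
#' aggregation adds `ceiling(truncate * rho)`; a chunk halo covering their sum
#' makes chunked output equal to dense output.
#'
#' @inheritParams compute_gradients
#' @param rho Integration scale in voxels.
#' @export
sta_support <- function(sigma, rho, truncate = 4) {
  as.integer(ceiling(truncate * sigma) + ceiling(truncate * rho))
}

conv_sep <- function(arr, kernels, mode = "reflect", cval = 0) {
  m <- boundary_mode_code(mode)
  for (a in 1:3)
    arr <- .conv3d_axis(arr, dim(arr), kernels[[a]], a, m, cval)
  arr
}

#' Smoothed intensity gradients
#'
#' Partial derivatives of the sigma-smoothed image along x, y, z, implemented
#' as separable correlation with a derivative-of-Gaussian kernel along the
#' derivative axis and Gaussian kernels along the other two.
#'
#' @param vol An [intensity_volume()] or 3D array.
#' @param sigma Noise scale in voxels (> 0); sets the feature scale the
#'   gradient responds to.
#' @param truncate Kernel cutoff in standard deviations.
#' @param boundary_mode Volume-border handling (default `"reflect"`).
#' @return 4D array `(nx, ny, nz, 3)` of class `gradient_field` with
#'   attributes `sigma` and `truncate`.
#' @export
compute_gradients <- function(vol, sigma = 2, truncate = 4,
                              boundary_mode = "reflect") {
  arr <- if (is_intensity_volume(vol)) vol$data else vol
  stopifnot(is.array(arr), length(dim(arr)) == 3L, sigma > 0)
  g <- gaussian_kernel(sigma, truncate)
  dg <- gaussian_deriv_kernel(sigma, truncate)
  d <- dim(arr)
  out <- array(0, dim = c(d, 3L))
  for (a in 1:3) {
    ks <- list(g, g, g)
    ks[[a]] <- dg
    out[, , , a] <- conv_sep(arr, ks, boundary_mode)
  }
  structure(out, class = "gradient_field", sigma = sigma, truncate = truncate)
}

#' Structure tensor from a gradient field
#'
#' Per-voxel dyadic product of the gradient with itself, each of the six
#' unique components smoothed with a Gaussian of standard deviation `rho`
#' (the integration scale). The result is symmetric positive semi-definite
#' up to float rounding.
#'
#' @param grad A `gradient_field` from [compute_gradients()] (possibly
#'   vessel-masked by [mask_gradients()]).
#' @param rho Integration scale in voxels (> 0).
#' @param truncate Kernel cutoff in standard deviations.
#' @param boundary_mode Volume-border handling.
#' @return 4D array `(nx, ny, nz, 6)` of class `structure_tensor_field`;
#'   component order `xx, xy, xz, yy, yz, zz`.
#' @export
compute_structure_tensor <- function(grad, rho = 4, truncate = 4,
                                     boundary_mode = "reflect") {
  stopifnot(length(dim(grad)) == 4L, dim(grad)[4] == 3L, rho > 0)
  kr <- gaussian_kernel(rho, truncate)
  ks <- list(kr, kr, kr)
  d <- dim(grad)[1:3]
  gx <- grad[, , , 1]; gy <- grad[, , , 2]; gz <- grad[, , , 3]
  out <- array(0, dim = c(d, 6L))
  out[, , , 1] <- conv_sep(gx * gx, ks, boundary_mode)
  out[, , , 2] <- conv_sep(gx * gy, ks, boundary_mode)
  out[, , , 3] <- conv_sep(gx * gz, ks, boundary_mode)
  out[, , , 4] <- conv_sep(gy * gy, ks, boundary_mode)
  out[, , , 5] <- conv_sep(gy * gz, ks, boundary_mode)
  out[, , , 6] <- conv_sep(gz * gz, ks, boundary_mode)
  structure(out, class = "structure_tensor_field", rho = rho,
            sigma = attr(grad, "sigma"))
}

#' Eigendecomposition of a structure tensor field
#'
#' Returns sorted eigenvalues (`l1 >= l2 >= l3`) and the unit eigenvector of
#' the smallest eigenvalue, `v3` — the direction of minimal local intensity
#' variation, taken as the fiber axis. `v3` is axial (v and -v equivalent);
#' its sign is canonicalized so the largest-magnitude component is positive.
#'
#' Voxels where the orientation is ill-defined are flagged `undefined`:
#' either the two smallest eigenvalues are nearly degenerate
#' (`(l2 - l3) / l1 < degen_tol`, so v3 is arbitrary within a plane) or the
#' tensor trace falls below `trace_floor` (no meaningful gradient signal —
#' in near-uniform regions minor intensity fluctuations generate spurious
#' gradients). Flagged voxels are excluded from orientation histograms and
#' from tractography seeding downstream.
#'
#' @param S A `structure_tensor_field`.
#' @param degen_tol Relative eigenvalue-degeneracy tolerance (default 1e-3).
#' @param trace_floor Absolute trace floor; the [sta()] wrapper sets it to
#'   `1e-6 * (intensity range)^2`. Default 0 (disabled).
#' @return Object of class `eigen_field`: list with `lambda` (4D, 3
#'   channels), `v3` (4D, 3 channels), `undefined` (logical 3D array).
#' @export
eigendecompose <- function(S, degen_tol = 1e-3, trace_floor = 0) {
  stopifnot(length(dim(S)) == 4L, dim(S)[4] == 6L)
  d <- dim(S)[1:3]
  n <- prod(d)
  Sm <- matrix(as.numeric(S), nrow = n, ncol = 6L)
  res <- .eig3_field(Sm)
  lam <- res$lambda
  tr <- lam[, 1] + lam[, 2] + lam[, 3]
  # PSD up to float tolerance; clamp residual negatives to zero
  if (any(lam[, 3] < -1e-8 * pmax(tr, 0) - 1e-12))
    stop("structure tensor has eigenvalues below the PSD tolerance")
  lam[lam < 0] <- 0
  undef <-
    ((lam[, 2] - lam[, 3]) < degen_tol * pmax(lam[, 1], .Machine$double.xmin)) |
    (tr < trace_floor)
  structure(list(
    lambda = array(lam, dim = c(d, 3L)),
    v3 = array(res$v3, dim = c(d, 3L)),
    undefined = array(undef, dim = d)),
    class = "eigen_field")
}

#' @export
print.eigen_field <- function(x, ...) {
  d <- dim(x$undefined)
  cat(sprintf("<eigen_field> %d x %d x %d voxels, %.1f%% undefined orientation\n",
              d[1], d[2], d[3], 100 * mean(x$undefined)))
  invisible(x)
}

#' Tensor shape and anisotropy maps
#'
#' From the sorted eigenvalues: the linear, planar and spherical shape
#' measures
#' `Cl = (l1 - l2) / l1`, `Cp = (l2 - l3) / l1`, `Cs = l3 / l1`
#' (which sum to one wherever `l1 > 0`), and fractional anisotropy
#' `FA = sqrt(3/2 * sum((li - lbar)^2) / sum(li^2))` with
#' `lbar = (l1 + l2 + l3) / 3`, in \[0, 1\].
#' Voxels with `l1 = 0` get all-zero metrics and are flagged undefined.
#'
#' @param E An `eigen_field` from [eigendecompose()].
#' @return Object of class `scalar_maps`: list of 3D arrays `Cl`, `Cp`,
#'   `Cs`, `FA` and logical `undefined`.
#' @export
shape_metrics <- function(E) {
  stopifnot(inherits(E, "eigen_field"))
  lam <- E$lambda
  d <- dim(lam)[1:3]
  l1 <- lam[, , , 1]; l2 <- lam[, , , 2]; l3 <- lam[, , , 3]
  tr <- l1 + l2 + l3
  if (any(l3 < -1e-8 * pmax(tr, 0) - 1e-12))
    stop("negative eigenvalue beyond PSD tolerance")
  zero <- l1 <= 0
  l1s <- ifelse(zero, 1, l1)  # avoid 0/0; overwritten below
  Cl <- (l1 - l2) / l1s
  Cp <- (l2 - l3) / l1s
  Cs <- l3 / l1s
  lbar <- tr / 3
  denom <- l1^2 + l2^2 + l3^2
  denom[zero] <- 1
  FA <- sqrt(1.5 * ((l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2) / denom)
  FA <- pmin(FA, 1)
  Cl[zero] <- 0; Cp[zero] <- 0; Cs[zero] <- 0; FA[zero] <- 0
  structure(list(Cl = Cl, Cp = Cp, Cs = Cs, FA = FA,
                 undefined = zero | E$undefined),
            class = "scalar_maps")
}

#' Full structure tensor analysis
#'
#' One-call orchestration of gradients -> (optional vessel masking) ->
#' tensor aggregation -> eigendecomposition -> scalar maps, either dense in
#' memory or chunk-wise with halo padding via [map_with_halo()] (the chunked
#' path computes the tensor per chunk — the eigendecomposition is voxel-wise
#' and runs on the assembled field).
#'
#' @param vol An [intensity_volume()].
#' @param sigma,rho Noise and integration scales in voxels (defaults 2 and 4).
#' @param truncate Kernel cutoff in standard deviations (default 4).
#' @param mask Optional 0/1 vessel mask array, same shape as the volume.
#' @param mask_mode `"gradient"` (suppress gradients under the dilated mask —
#'   the recommended approach), or `"pre"` (zero intensities before the
#'   tensor; kept to demonstrate the intensity-void artifact it produces).
#' @param dilate_vox Mask dilation radius in voxels before gradient
#'   suppression (default 1, covering the vessel wall's own edge gradients).
#' @param plan Optional [chunk_plan()]; `NULL` runs dense.
#' @param boundary_mode Volume-border handling.
#' @param degen_tol Degeneracy tolerance passed to [eigendecompose()].
#' @return List of class `sta_result`: `tensor`, `eigen`, `metrics`,
#'   and the scales used.
#' @export
sta <- function(vol, sigma = 2, rho = 4, truncate = 4, mask = NULL,
                mask_mode = c("gradient", "pre"), dilate_vox = 1L,
                plan = NULL, boundary_mode = "reflect", degen_tol = 1e-3) {
  stopifnot(is_intensity_volume(vol))
  mask_mode <- match.arg(mask_mode)
  arr <- vol$data
  rng2 <- (max(arr) - min(arr))^2

  dmask <- NULL
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(arr)))
      stop("mask shape does not match the volume")
    if (mask_mode == "pre") {
      arr <- arr * (1 - mask)
      mask <- NULL
    } else {
      dmask <- dilate_mask(mask, dilate_vox)
    }
  }

  support <- sta_support(sigma, rho, truncate)
  # The pipeline is defined on the boundary-extended image: the volume is
  # padded by the filter support (reflect by default), gradients and tensor
  # smoothing run on the extension, and the padding is discarded. The dense
  # path is the degenerate single-chunk case, so results are independent of
  # the chunk layout by construction.
  if (is.null(plan)) plan <- chunk_plan(dim(arr), support, boundary_mode)
  op <- function(padded, info) {
    g <- compute_gradients(padded, sigma, truncate, boundary_mode)
    if (!is.null(mask)) {
      msub <- extract_by_mapped_indices(dmask, info$index, 0)
      g <- mask_gradients(g, msub, dilate_vox = 0L)
    }
    compute_structure_tensor(g, rho, truncate, boundary_mode)
  }
  S <- map_with_halo(arr, plan, op, support)
  S <- structure(S, class = "structure_tensor_field", rho = rho, sigma = sigma)
  E <- eigendecompose(S, degen_tol = degen_tol, trace_floor = 1e-6 * rng2)
  M <- shape_metrics(E)
  structure(list(tensor = S, eigen = E, metrics = M,
                 sigma = sigma, rho = rho, truncate = truncate,
                 voxel_size_um = vol$voxel_size_um),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  d <- dim(x$eigen$undefined)
  cat(sprintf(paste0("<sta_result> %d x %d x %d voxels (sigma %g, rho %g); ",
                     "median FA %.3f\n"),
              d[1], d[2], d[3], x$sigma, x$rho,
              stats::median(x$metrics$FA[!x$metrics$undefined])))
  invisible(x)
}

# Chebyshev-ball (box) binary dilation by r voxels, separable per axis.
dilate_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r <= 0L) return(mask != 0)
  m <- mask != 0
  d <- dim(m)
  for (a in 1:3) {
    acc <- m
    for (s in seq_len(r)) {
      acc <- acc | shift_array(m, a, s) | shift_array(m, a, -s)
    }
    m <- acc
  }
  m
}

shift_array <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1L) { out[dst, , ] <- m[src, , ] }
  else if (axis == 2L) { out[, dst, ] <- m[, src, ] }
  else { out[, , dst] <- m[, , src] }
  out
}
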