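## Vascular-confound quantification and suppression: gradient-level masking,
## Angular Correlation Coefficient of fODF pairs, paired statistics.

#' Suppress intensity gradients under a vessel mask
#'
#' Zeroes the gradient vectors at every voxel covered by the (optionally
#' dilated) vessel mask, so vessels contribute no orientation signal to the
#' structure tensor while leaving the surrounding intensity field untouched.
#' This avoids the artificial intensity voids — and the spurious strong
#' gradients at their walls — that zeroing intensities before the tensor
#' computation creates. A one-voxel default dilation covers the vessel
#' wall's own edge gradients.
#'
#' @param grad A `gradient_field` from [compute_gradients()].
#' @param mask 0/1 vessel mask, same 3D shape as the gradient grid.
#' @param dilate_vox Dilation radius in voxels applied to the mask before
#'   suppression (default 1).
#' @return A `gradient_field` with masked gradients.
#' @export
mask_gradients <- function(grad, mask, dilate_vox = 1L) {
  stopifnot(length(dim(grad)) == 4L, dim(grad)[4] == 3L)
  if (!identical(dim(mask)[1:3], dim(grad)[1:3]))
    stop("mask shape does not match the gradient field")
  m <- dilate_mask(mask, dilate_vox)
  if (any(m)) for (a in 1:3) {
    comp <- grad[, , , a]
    comp[m] <- 0
    grad[, , , a] <- comp
  }
  grad
}

#' Zero intensities under a vessel mask (pre-tensor masking)
#'
#' Removes vascular structures from the volume before the structure tensor is
#' computed, by multiplying with the inverted mask. Provided for comparison:
#' the voids it creates generate artificially strong gradients at vessel
#' boundaries (see [vessel_shell_energy()]), which is why gradient-level
#' masking is the recommended approach.
#'
#' @param vol An [intensity_volume()].
#' @param mask 0/1 vessel mask, same shape.
#' @return A masked [intensity_volume()].
#' @export
mask_volume_pre_tensor <- function(vol, mask) {
  stopifnot(is_intensity_volume(vol))
  if (!identical(dim(mask), dim(vol$data)))
    stop("mask shape does not match the volume")
  intensity_volume(vol$data * (1 - (mask != 0)), vol$voxel_size_um)
}

#' Gradient energy in a shell around vessels
#'
#' Sum of squared gradient magnitudes over the voxels within `shell_vox`
#' voxels of the vessel mask but outside the mask itself — the region where
#' pre-tensor masking injects artificial wall gradients.
#'
#' @param grad A `gradient_field`.
#' @param mask 0/1 vessel mask.
#' @param shell_vox Shell thickness in voxels (default 2).
#' @return Scalar energy.
#' @export
vessel_shell_energy <- function(grad, mask, shell_vox = 2L) {
  m <- mask != 0
  shell <- dilate_mask(m, shell_vox) & !m
  g2 <- grad[, , , 1]^2 + grad[, , , 2]^2 + grad[, , , 3]^2
  sum(g2[shell])
}

#' Angular Correlation Coefficient of two fODFs
#'
#' Normalized inner product of the spherical-harmonic coefficient vectors
#' over orders l >= 1 (the l = 0 term, the isotropic mean, is excluded), on a
#' scale of -1 to 1: 1 for identical angular shape, -1 for opposite. Returns
#' `NA` if either fODF has zero l >= 1 energy (perfectly isotropic), since
#' the angular shape is then undefined.
#'
#' @param u,v Coefficient vectors in the same real even-order basis and lmax.
#' @param lmax,even_only Basis parameters (defaults 8, even-only).
#' @return ACC scalar in \[-1, 1\], or `NA`.
#' @export
angular_correlation <- function(u, v, lmax = 8L, even_only = TRUE) {
  if (length(u) != length(v))
    stop("coefficient vectors have different lengths (basis mismatch)")
  nc <- n_sh_coef(lmax, even_only)
  if (length(u) != nc)
    stop("coefficient length ", length(u), " does not match lmax ", lmax)
  if (anyNA(u) || anyNA(v)) return(NA_real_)
  u1 <- u[-1L]; v1 <- v[-1L]  # drop the single l = 0 coefficient
  nu <- sqrt(sum(u1^2)); nv <- sqrt(sum(v1^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u1 * v1) / (nu * nv)
}

#' Paired comparison of scalar metrics with and without vessel masking
#'
#' Given per-supervoxel metric pairs (with vessels present vs masked),
#' computes the paired two-sided t-test, Cohen's d on the paired differences
#' (`mean(diff) / sd(diff)`), and the Wilcoxon signed-rank test (zero
#' differences dropped, average ranks for ties, normal approximation). These
#' are descriptive outputs; no multiple-testing correction is applied.
#'
#' @param with_vessels,masked Numeric vectors, aligned by supervoxel,
#'   length >= 2.
#' @return Object of class `paired_comparison`: list with `n`, `t`,
#'   `t_p`, `cohens_d` (`0` when all differences are zero, `NA` with a note
#'   when the differences are constant but nonzero), `wilcoxon_V`,
#'   `wilcoxon_p`, and the differences.
#' @export
paired_metric_tests <- function(with_vessels, masked) {
  if (length(with_vessels) != length(masked))
    stop("pair vectors must have equal length")
  n <- length(with_vessels)
  if (n < 2L) stop("need at least 2 pairs")
  diffs <- with_vessels - masked
  sd_d <- stats::sd(diffs)
  if (all(diffs == 0)) {
    d <- 0
    tt <- list(statistic = c(t = 0), p.value = 1)
    wil <- list(statistic = c(V = NA_real_), p.value = 1)
  } else {
    d <- if (sd_d == 0) NA_real_ else mean(diffs) / sd_d
    tt <- if (sd_d == 0) list(statistic = c(t = NA_real_), p.value = NA_real_)
          else stats::t.test(with_vessels, masked, paired = TRUE)
    wil <- suppressWarnings(
      stats::wilcox.test(with_vessels, masked, paired = TRUE, exact = FALSE,
                         correct = TRUE))
  }
  structure(list(n = n, t = unname(tt$statistic), t_p = tt$p.value,
                 cohens_d = d,
                 d_degenerate = is.na(d),
                 wilcoxon_V = unname(wil$statistic), wilcoxon_p = wil$p.value,
                 diffs = diffs),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(paste0("<paired_comparison> n = %d pairs\n",
                     "  paired t: t = %s, p = %s\n",
                     "  Cohen's d: %s%s\n",
                     "  Wilcoxon signed-rank: V = %s, p = %s\n"),
              x$n, format(x$t), format(x$t_p),
              format(x$cohens_d),
              if (isTRUE(x$d_degenerate)) " (degenerate: constant nonzero differences)" else "",
              format(x$wilcoxon_V), format(x$wilcoxon_p)))
  invisible(x)
}

#' Per-supervoxel ACC versus vessel volume fraction
#'
#' Pairs each supervoxel's ACC between the unmasked and masked fODF with the
#' supervoxel's vessel volume fraction (computed from the fine-resolution
#' mask), the basis of the vessel-robustness analysis. Supervoxels with an
#' undefined ACC (isotropic fODF) are reported as `NA` and counted in the
#' `n_undefined_acc` QC field; empty supervoxels are dropped.
#'
#' @param sh_unmasked,sh_masked `sh_field`s on the same supervoxel grid.
#' @param vessel_mask Fine-resolution 0/1 mask.
#' @return Object of class `acc_table`: data.frame with columns `sv` (linear
#'   index), `vessel_fraction_pct`, `acc`, plus attributes.
#' @export
acc_vs_vessel_fraction <- function(sh_unmasked, sh_masked, vessel_mask) {
  stopifnot(inherits(sh_unmasked, "sh_field"), inherits(sh_masked, "sh_field"))
  if (!identical(sh_unmasked$sv_dim, sh_masked$sv_dim))
    stop("supervoxel grids do not match")
  if (sh_unmasked$lmax != sh_masked$lmax)
    stop("basis mismatch between the two fields")
  frac <- supervoxel_vessel_fraction(vessel_mask, sh_unmasked$edge_vox)
  n_sv <- prod(sh_unmasked$sv_dim)
  acc <- vapply(seq_len(n_sv), function(s)
    angular_correlation(sh_unmasked$coeffs[s, ], sh_masked$coeffs[s, ],
                        lmax = sh_unmasked$lmax), numeric(1))
  keep <- !(sh_unmasked$empty | sh_masked$empty)
  tab <- data.frame(sv = seq_len(n_sv),
                    vessel_fraction_pct = 100 * as.numeric(frac),
                    acc = acc)[keep, ]
  structure(tab, class = c("acc_table", "data.frame"),
            n_undefined_acc = sum(is.na(tab$acc)))
}

#' Stratum summaries of an ACC table
#'
#' Minimum and median ACC within vessel-fraction strata.
#'
#' @param tab An `acc_table` from [acc_vs_vessel_fraction()].
#' @param breaks_pct Stratum boundaries in percent (default
#'   `c(0, 1, 4, 10)`: strata (0,1\], (1,4\], (4,10\] plus an exact-zero
#'   stratum).
#' @return data.frame with one row per non-empty stratum: bounds, n,
#'   `median_acc`, `min_acc`.
#' @export
acc_stratum_summary <- function(tab, breaks_pct = c(0, 1, 4, 10)) {
  stopifnot(inherits(tab, "acc_table") || is.data.frame(tab))
  tab <- tab[!is.na(tab$acc), ]
  lowers <- c(-Inf, breaks_pct[-length(breaks_pct)])
  uppers <- breaks_pct
  out <- list()
  for (i in seq_along(uppers)) {
    sel <- tab$vessel_fraction_pct > lowers[i] &
           tab$vessel_fraction_pct <= uppers[i]
    if (i == 1L) sel <- tab$vessel_fraction_pct <= uppers[1]  # includes 0
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      lower_pct = if (i == 1L) 0 else lowers[i], upper_pct = uppers[i],
      n = sum(sel),
      median_acc = stats::median(tab$acc[sel]),
      min_acc = min(tab$acc[sel]))
  }
  do.call(rbind, out)
}
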