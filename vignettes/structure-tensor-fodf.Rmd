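---
title: "Fiber orientation mapping from label-free tomography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber orientation mapping from label-free tomography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrect)
```

# The problem

Label-free X-ray phase-contrast tomography of soft tissue (for example
synchrotron scans of whole human brains) resolves white-matter fascicles as
bright striated textures and blood vessels as dark tubular voids, at
micrometer isotropic resolution. Unlike diffusion MRI, which infers axonal
orientation indirectly from water diffusion in millimeter-scale voxels, the
orientation information here is carried directly by the image texture.
`fibrect` turns such volumes into:

1. voxel-wise fiber orientations and anisotropy maps (structure tensor
   analysis, STA),
2. supervoxel fiber Orientation Distribution Functions (fODFs) represented by
   real even-order spherical harmonics, with Generalized Fractional
   Anisotropy (GFA),
3. probabilistic streamline tractograms, and
4. a quantitative analysis of how much the (simultaneously visible)
   vasculature confounds the orientation estimates, together with a
   gradient-level vessel-masking procedure that suppresses it.

Because real tomographic volumes of this kind are hundreds of gigabytes and
not redistributable, every stage is validated against a synthetic phantom
generator with exact ground truth; the phantom module is first-class,
tested code, not a fixture.

# The model

## Structure tensor

The image $I$ is smoothed with an isotropic Gaussian $K_\sigma$ and
differentiated (implemented as separable correlation with a
derivative-of-Gaussian kernel), giving the gradient field
$\nabla I_\sigma = (\partial_x I_\sigma, \partial_y I_\sigma, \partial_z I_\sigma)$.
The gradient square tensor is the voxel-wise dyadic product
$\nabla I_\sigma \nabla I_\sigma^\top$, and the structure tensor is its
component-wise Gaussian aggregation at the integration scale $\rho$:

$$S_\rho = K_\rho * \left(\nabla I_\sigma \nabla I_\sigma^\top\right).$$

$\sigma$ sets the feature scale the gradient responds to (noise scale);
$\rho$ sets the neighborhood over which orientation evidence is pooled.
Defaults are $\sigma = 2$ and $\rho = 4$ voxels; both are configurable and
expressed in voxel units (physical-unit scales can be converted through the
volume's voxel size at the configuration layer).

The eigendecomposition $S_\rho v_i = \lambda_i v_i$ with
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ yields the fiber axis as
$v_3$, the direction of minimal intensity variation: along a fiber the
texture is constant, across it the striations vary. $v_3$ is axial
($v_3 \equiv -v_3$); we canonicalize its sign so the largest-magnitude
component is positive, a deterministic convention that downstream code must
not rely on beyond testing convenience.

From the sorted eigenvalues the tensor-shape measures are
$C_l = (\lambda_1-\lambda_2)/\lambda_1$,
$C_p = (\lambda_2-\lambda_3)/\lambda_1$,
$C_s = \lambda_3/\lambda_1$ (summing to one whenever $\lambda_1 > 0$), and

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}
\frac{(\lambda_1-\hat\lambda)^2 + (\lambda_2-\hat\lambda)^2 + (\lambda_3-\hat\lambda)^2}
{\lambda_1^2+\lambda_2^2+\lambda_3^2}}, \qquad
\hat\lambda = \tfrac{1}{3}(\lambda_1+\lambda_2+\lambda_3).$$

Note the orientation of *minimal* eigenvalue is the fiber axis — the tensor
measures gradient energy, so a coherent bundle has two large eigenvalues
(gradients across the striations) and one near-zero eigenvalue (along the
fiber). A perfectly coherent bundle therefore has $\mathrm{FA} =
\sqrt{1/2} \approx 0.707$, not 1.

## Degenerate orientations

$v_3$ is well-defined only when $\lambda_2 > \lambda_3$. Voxels with
$(\lambda_2-\lambda_3)/\lambda_1 < 10^{-3}$, or with tensor trace below
$10^{-6} \times (\text{intensity range})^2$ (no meaningful gradient signal:
in near-uniform tissue, minor intensity fluctuations generate spurious
gradients), are flagged *undefined* and excluded from orientation
histograms and seeding. The degeneracy threshold is a package choice — a
floor of this kind is needed because an isotropic tensor's $v_3$ is
arbitrary within a plane, and any value would otherwise silently
contaminate the histograms.

## fODFs and GFA

The fine-scale $v_3$ field is partitioned into cubic supervoxels (default
800 µm, matching a typical dMRI voxel; any whole multiple of the voxel size
works, and halving the edge to 400 µm preserves the dominant axes while
refining detail). Within each supervoxel the non-flagged orientations are
binned on the sphere in an equal-angle grid, azimuth
$\phi \in (0, 2\pi) \times$ elevation $\theta \in (0,\pi)$ (default
$16 \times 32$). Each orientation contributes to its bin *and* the
antipodal bin, so the histogram is exactly antipodally symmetric and totals
twice the contributing voxel count.

The histogram is converted to a solid-angle density (equal-angle bins
over-weight the poles otherwise) and fit by solid-angle-weighted linear
least squares to the real orthonormal spherical-harmonic basis of even
orders $l \le 8$ (45 coefficients):

$$f(\theta,\phi) = \sum_{l=0,2,\dots,8}\ \sum_{m=-l}^{l} c_{lm} Y_{lm}(\theta,\phi).$$

Even orders only: orientations are axial, so the symmetrized input has no
odd-order energy, and dropping the odd terms halves the parameter count and
conditions the fit — the standard convention for dMRI fODFs, which the
cross-modal comparison this representation exists for requires anyway. A
ridge of $10^{-8}$ stabilizes the solve; supervoxels with fewer occupied
bins than coefficients (for example perfectly coherent noise-free phantoms,
where all mass sits in two bins) are refit with ridge $10^{-3}$ under a
warning. Coefficients are scaled so $f$ integrates to one; every
coefficient-level analysis downstream (ACC) is scale-invariant, so this is
cosmetic but fixes cross-supervoxel comparability.

GFA summarizes how peaked an fODF is, from amplitudes $\Psi_i$ sampled on a
fixed set of $n = 200$ Fibonacci-spiral directions (any approximately
uniform set with $n \ge 100$ works; the set is fixed per field for
comparability), clipped at zero:

$$\mathrm{GFA} = \frac{\mathrm{std}(\Psi)}{\mathrm{rms}(\Psi)}
 = \sqrt{\frac{n \sum_i (\Psi_i - \bar\Psi)^2}{(n-1)\sum_i \Psi_i^2}}.$$

It is 0 for a constant fODF, exactly 1 when a single sample is nonzero, and
invariant to positive rescaling. Unlike FA, GFA stays high in crossing
regions — the fODF keeps distinct peaks even when the tensor becomes more
isotropic — which is why the tractography stopping rule uses GFA.

## Tractography

Streamlines are seeded at the centers (optionally jittered) of supervoxels
whose mean fine-voxel FA exceeds 0.42, a threshold near the median FA that
separates coherent white matter from more isotropic surroundings.
Propagation is probabilistic and bidirectional: at each step a direction is
drawn from the local fODF (nearest supervoxel, no interpolation — the fODF
grid *is* the supervoxel grid; trilinear coefficient interpolation would be
a straightforward extension) evaluated on an antipodally symmetric 724-point
direction set, restricted to the cone within 30° of the incoming direction;
the first draw is unrestricted and the second half-track starts along its
antipode. The step is a quarter of the supervoxel edge. Tracks stop on GFA
below 0.7 (checked at every step), volume exit, or zero sampling mass in
the cone; streamlines shorter than 4 steps are discarded as seed-noise
stubs.

Two numerical choices matter here. First, negative SH lobes are clipped to
zero at evaluation time only — raw coefficients are kept unclipped for
coefficient-level analyses. Second, amplitudes below 0.1 of the
supervoxel's maximum are excluded from the sampling mass (the convention of
probabilistic ODF trackers). The band-limited ($l \le 8$) representation of
a near-delta orientation distribution rings: it has a main lobe of roughly
12° half-width plus oscillatory side lobes, and sampling the raw clipped
amplitude would send a substantial fraction of steps into the side lobes.
The relative threshold confines sampling to the physically meaningful
lobes; it is configurable (`pmf_threshold`) and setting it to zero restores
pure amplitude-proportional sampling.

All randomness flows from a single integer seed; tractograms are bitwise
reproducible on a platform.

## Vessel masking and the Angular Correlation Coefficient

Vessels appear as dark tubes whose walls generate strong gradients
perpendicular to the vessel axis — exactly the signature of a fiber along
the vessel. Two suppression strategies are implemented:

- **Pre-tensor masking** zeroes the intensities under the vessel mask
  before STA. This creates intensity voids whose edges generate *artificial*
  strong gradients: measured as gradient energy in a 2-voxel shell around
  the vessels, pre-tensor masking consistently injects several times more
  energy than it removes. It is provided to demonstrate the artifact.
- **Gradient-level masking** (recommended, and the default in the
  comparison pipeline) computes gradients from the original volume and
  zeroes the gradient *vectors* under the mask before tensor aggregation.
  Vessels then contribute no orientation evidence and no voids are created.
  The mask is dilated by 1 voxel first so the vessel wall's own edge
  gradients (which have support $\sim\sigma$) are covered; the dilation
  radius is configurable.

The agreement between fODFs computed with and without masking is measured
by the Angular Correlation Coefficient over their SH coefficients $u, v$,
excluding $l = 0$:

$$\mathrm{ACC} = \frac{\sum_{l\ge1,m} u_{lm} v_{lm}}
{\left(\sum_{l\ge1,m} u_{lm}^2\right)^{1/2} \left(\sum_{l\ge1,m} v_{lm}^2\right)^{1/2}} \in [-1, 1].$$

ACC is computed from the raw fitted coefficients; it is invariant to
positive rescaling, so the $\int f = 1$ normalization does not affect it.
A perfectly isotropic fODF has zero $l \ge 1$ energy and undefined angular
shape; such supervoxels are reported as missing and counted in a QC field
rather than silently assigned a value. Scalar metrics (e.g. mean supervoxel
FA) are compared between the masked and unmasked conditions with a paired
two-sided t-test, Cohen's d on the paired differences, and a Wilcoxon
signed-rank test; these are descriptive outputs and no multiple-testing
correction is applied, since a single global comparison is reported.

# The phantom generator

`generate_fiber_phantom()` emulates the three features of the real data the
pipeline's correctness depends on; each is a deliberate idealization:

- **Coherent bundles**: bright striations on a mid-gray background,
  modeled as sinusoidal intensity modulation along two orthogonal
  directions perpendicular to the bundle axis (period = `spacing_vox`,
  default 8 voxels). A sinusoidal (rather than discrete-tube) model gives
  smooth, differentiable gradients — the regime STA assumes — and makes the
  ground truth exact: the noise-free gradient is everywhere perpendicular
  to the fiber axis. Two modulation directions are required: a single one
  would leave the tensor rank-1 and $v_3$ degenerate.
- **Interdigitated crossings**: bundles can be confined to periodic slabs,
  so two orthogonal bundles in interleaved slabs reproduce a pons-like
  weave; at the supervoxel scale the fODF must then resolve both axes.
  Overlapping territories are summed and clipped to the 16-bit range, with
  both axes recorded in the truth and the region flagged as crossing.
- **Vessels**: dark capsules (voxels within a radius of a centerline
  polyline), with the mask recording exactly the carved voxels, so
  per-supervoxel vessel fractions are exact counts, not estimates.

Intensities follow the conventions of the real data: fibers bright,
vessels dark, background mid-gray, 16-bit unsigned range (background
20 000, bundle amplitude 20 000, vessel intensity 2 000). Noise is additive
Gaussian only; its level is a free parameter because the noise statistics
of real phase-contrast reconstructions are not well characterized — the
validation experiments use 500 (2.5% of the bundle amplitude) as a
realistic operating point and 2 000 (10%) as a stress case. A separate
streak injector writes a bright capsule of stated width for
artifact-robustness experiments, mimicking the linear streaks near sharp
density transitions. The generator does *not* emulate X-ray physics,
reconstruction artifacts beyond the streak, partial-volume texture, or the
anatomical variety of real fascicles — passing phantom tests therefore
demonstrates the correctness of the computational pipeline, not the
biological fidelity of orientations recovered from any particular scan.

# Out-of-core processing

Filtering a volume chunk-by-chunk corrupts chunk seams unless each chunk is
loaded with a halo at least as wide as the filter support; the halo is
computed and discarded after the per-chunk computation. Kernels are
truncated at 4 standard deviations, so the STA support is
$\lceil 4\sigma \rceil + \lceil 4\rho \rceil$ voxels (gradient plus
aggregation). `map_with_halo()` refuses to run when the declared support
exceeds the plan's halo — silent seam artifacts are the failure mode the
interface exists to prevent.

The pipeline is *defined* on the boundary-extended image: the volume is
padded by the support (symmetric reflection by default), the whole cascade
runs on the extension, and the padding is discarded. This makes the output
independent of the chunk layout by construction — the dense path is just
the single-chunk case — and the tests require agreement within $10^{-5}$
relative across layouts (float accumulation order may differ). Reflection
was chosen over constant padding because a constant frame would inject
spurious boundary gradients into the tensor, exactly the artifact the
vessel analysis shows for intensity voids. A subtlety worth recording:
defining the pipeline instead as "apply each filter to the full volume with
reflected boundaries stage by stage" is *not* equivalent, because the
derivative is antisymmetric under reflection while the tensor components
are not; the extended-image definition avoids that ambiguity.

Volumes read and write through a native chunked directory store (flat
little-endian float64 chunk files plus JSON metadata, bit-exact
round-trip), single-file NIfTI-1 (for viewing FA and scalar maps in
standard tools), and read-only TIFF slice stacks. The pipeline assumes
isotropic voxels; anisotropic NIfTI headers are rejected rather than
silently averaged, and TIFF stacks require an explicit voxel size. No
intensity normalization is applied before STA by default.

# Problem sizes and validation experiments

The validation suite generates all inputs in code, at sizes chosen so each
experiment exercises the property it tests:

- orientation recovery, fODF peaks, tractography: $64^3$ voxels at
  12.5 µm, supervoxels of 16–64 voxels;
- chunk-layout independence: $96^3$, chunks $32^3$ and $48\times96\times24$;
- vessel robustness: $192^3$ at 12.5 µm with 800 µm-equivalent (64-voxel)
  supervoxels and straight transverse vessels of radii 3.6, 7.2 and 11.4
  voxels, giving supervoxel vessel fractions of ~1%, ~4% and ~10% —
  spanning the range from typical cerebral vascular volume (~4%) to its
  upper extreme. On this phantom the stratum-median ACC between masked and
  unmasked fODFs stays above 0.99 up to the 10% stratum and decreases
  monotonically with vessel fraction, and transverse vessels are the
  worst case: a vessel parallel to the bundle confounds the same axis and
  barely moves the ACC.

`scripts/acceptance.R` re-runs the vessel-robustness experiment end to end
and reports the median ACC among supervoxels with vessel fraction ≤ 10%.

# Known limitations

- Orientation accuracy degrades near the degeneracy floor; in near-uniform
  regions the estimates are flagged rather than repaired (no tensor
  regularization beyond Gaussian smoothing, no multi-scale pyramids).
- The fODF fit is a plain least-squares histogram fit; no deconvolution or
  sharpening, so peak width is set by the $l \le 8$ band limit (~12°).
  Closely separated crossing axes (< ~25°) will merge.
- Tracking is nearest-supervoxel and purely local; no anatomical
  constraints, no streamline filtering beyond the minimum-length rule.
- The equal-angle histogram concentrates perfectly coherent noise-free
  fields into one or two bins, where the fitted peak can sit a few degrees
  off-axis (bin-center quantization); any realistic noise level spreads
  the mass and removes the bias.
- Chunked processing is single-process; the chunk loop is the natural
  parallelization point but no multi-node execution is provided.
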