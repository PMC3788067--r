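---
title: "Validating tractography against tracer histology on a synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tractography against tracer histology on a synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Streamline counts from diffusion-tensor tractography are widely used as a
proxy for anatomical connection strength, on the hypothesis that the number
of streamlines connecting two cortical regions is proportional to the number
of axons connecting them. Testing that hypothesis requires a ground truth
that diffusion MRI cannot provide: anterograde/retrograde tracer injections,
histological sectioning, and fiber counting at the white/gray matter (WGM)
interface, followed by registration of the histology back into the diffusion
space so that both modalities can be compared region by region and voxel by
voxel.

`tracerval` implements that comparison pipeline end to end — density
distribution maps (DDMs) of labeled fibers and of streamlines on the WGM
interface, mass-preserving transfer between coordinate spaces, and the
regional and voxelwise correlation statistics — and exercises it on a
synthetic phantom in which every quantity the histology would measure is
known exactly. The phantom stands in for a specimen: primate tracer data of
this kind are not publicly deposited, and the point of the package is the
*method*, which the phantom lets us verify property by property.

## The phantom

`default_phantom_config()` describes a flat-slab cortex in a 64^3 grid at
0.3 mm isotropic voxels (the voxel size of the emulated acquisition): a
gray-matter slab (FA about 0.13, radially oriented) on top of white matter
(background FA about 0.17), with background elsewhere. A 20 x 20 voxel
tracer-injection patch sits in the gray matter at the center; eight
projection ROIs are arranged on a ring around it. Each ROI is connected to
the injection by a white-matter bundle: a prolate tensor tube (FA about
0.84) that descends from under the injection, travels outward in its own
depth lane, and rises into the ROI. Bends are circular arcs with a 1.2 mm
radius, so the per-voxel turning angle (about 14 degrees per transit) stays
far below tracking stop angles.

Ground-truth axon counts per ROI are 2000, 750, 300, 120, 50, 20, 8 and 3 —
three orders of magnitude, emulating the dynamic range of real
cortico-cortical connection strengths. Two deliberate design choices:

* **Bundle calibers grow sublinearly with axon count** (radii 3.4 down to
  about 1 voxel). Strictly proportional cross-sections would make the
  largest bundle 20+ voxels wide or the smallest unresolvable; real tract
  calibers do not scale linearly with axon counts either (packing density
  varies). Streamline counts are therefore proportional to cross-sectional
  area, not to axon count, which is exactly the kind of bias the comparison
  statistics are meant to quantify; the Pearson correlation on this design
  is high but not 1.
* **Every caliber is at least about one voxel** and the vertical bundle
  columns are snapped onto the voxel-center lattice. Both are resolvability
  conditions: a sub-voxel tube is not traversable by a tracker that follows
  per-voxel directions, and the phantom's contract is that every true
  pathway is recoverable at the acquisition resolution.

Where bundles overlap, the voxel takes the orientation of the bundle with
the larger axon count ("winner-take-all"). This emulates single-tensor
partial-volume averaging, which is the crossing-fiber failure mechanism of
interest: with `crossing = TRUE` an occluding bundle is laid along the top
white-matter layer beneath the injection, across the largest bundle's
descending column. Its cross-section is anisotropic (wide in x, half a voxel
in z) so that it occludes exactly one voxel layer: seeds at depth
d_w = 0.3 mm land *in* the crossing layer and are deflected, while seeds at
d_w = 0.6 mm start below it and recover the pathway. This reproduces the
qualitative false-negative-versus-seed-depth structure seen in real data.

The gray-matter FA (about 0.13) is deliberately placed between the tracker's
start threshold (0.1) and stop threshold (0.2): gray-matter voxels may seed
streamlines, but propagation into gray matter terminates. That is the
configuration the deterministic scheme states (start FA below stop FA), and
it is what makes the seed-depth extension d_w matter.

## Signal simulation and tensor fitting

The acquisition scheme is one b = 0 volume plus 31 directions at
b = 1200 s/mm^2 (golden-angle hemisphere spread). The signal model is the
single-tensor Stejskal–Tanner decay `S = S0 exp(-b g' D g)`; Rician noise is
the magnitude of a complex Gaussian perturbation, with the default scale
S0/25 chosen to emulate an SNR-25 acquisition. Fitting is ordinary
(unweighted) log-linear least squares over all acquisitions jointly, the
"standard linear fitting" of common DTI software. Numerical choices:

* the signal is clamped at `1e-6 * S0` before the log (the Rician floor can
  produce values near zero);
* negative-eigenvalue fits are retained, with FA computed from eigenvalues
  clamped at zero;
* exactly equal eigenvalues short-circuit to FA = 0, so isotropic tensors
  give zero without floating-point residue;
* eigenvalues/principal directions are computed by a vectorized closed-form
  symmetric 3x3 eigensolver (trigonometric eigenvalues, Cayley–Hamilton
  principal vector) with a base-`eigen()` fallback for near-degenerate
  voxels; the test suite checks it against `eigen()` on random tensors;
* principal-direction sign is fixed by making the leading nonzero component
  nonnegative, so comparisons are deterministic.

Tensor reorientation under spatial maps uses preservation of principal
direction (PPD): eigenvalues are kept, the first eigenvector maps through
the local affine and is renormalized, the second is Gram–Schmidt-corrected.

## Tracking

**Deterministic (DS).** Fiber assignment by continuous tracking: from each
seed-voxel center with FA >= 0.1, propagate bidirectionally along the
per-voxel principal direction, changing direction at voxel boundaries,
terminating on entering a voxel with FA < 0.2, on a turning angle above 70
degrees, or on leaving the volume. A streamline that terminates for the FA
reason ends *within* the subthreshold voxel (vertex at the mid-transit
point), so cortical interface voxels where streamlines end are counted by
the crossing DDM — this matches counting "streamlines passing through or
terminating within" interface voxels. Antipodal eigenvector ambiguity is
resolved by aligning each voxel's direction with the incoming direction.

The seed region at depth d_w is the injection gray matter plus every white
matter voxel within d_w (Euclidean, voxel centers) of an interface voxel
beneath the injection; at 0.3 mm voxels, d_w = 0.3 and 0.6 mm add one and
two subjacent voxel layers. Streamline selection keeps streamlines
penetrating both the (extended) injection region and the interface beneath
it. Both seeding modes of common deterministic packages are provided
(seed-the-region, or whole-brain seeding followed by selection); the region
mode is the default because d_w is defined as a property of the seed region.

**Probabilistic.** A simplified sampler that honors the FSL-style contract
(seed/waypoint/termination masks, sample count, curvature threshold as a
minimum cosine of 0.2, 0.1 mm steps, modified Euler integration, distance
correction) on the single-tensor field: at each step the direction is drawn
from a symmetric angular distribution around the local principal direction
(tangential Gaussian with scale `orientation_sigma`; 0 degenerates to
deterministic propagation). This deliberately replaces the MCMC ball-and-
stick posterior of the original tool — the posterior model is out of scope;
what is preserved is the scheme's interface and its density semantics: the
returned voxel value is the number of retained sample visits times the mean
retained path length when distance correction is on. Samples whose step
fails the curvature threshold are terminated (the behavior of the emulated
tool) rather than redrawn. "Modified Euler" is a two-stage
predictor–corrector: the step direction is the normalized mean of the
sampled direction and the field direction at the predicted endpoint.

## Histology side

Synthetic micrographs (default 2048^2 px at 0.87 um/px, a scaled-down analog
of 4x magnification images) contain dark elongated fibers crossing a curved
WGM boundary, non-crossing fibers, round clutter, sub-threshold specks, an
illumination ramp, and Gaussian noise. Crossing fibers are placed at
stratified arc-length positions (guaranteed spacing; random within strata)
so planted objects remain resolvable as distinct connected components — the
pipeline counts components, and two overlapping fibers are one component in
any segmentation. Detection is the classic morphological pipeline: black
top-hat illumination correction (a white top-hat variant is provided for
bright-foreground images), Otsu global thresholding floored at a minimum
contrast of 0.2 (on a no-signal image Otsu would split the noise
distribution itself), connected components, and shape filters — area within
[20, 5000] px^2 and elongation perimeter^2/area >= 20 (a circle scores
4*pi ~ 12.6). The boundary is a parametric natural cubic spline through
ordered markers, rasterized to a 6 px band; crossing fibers are the
components whose masks intersect the band (mask AND), counted by full-object
centroid. The published cutoffs for the shape statistics are not available,
so the filter values are configuration with the above defaults.

The DDM grids the standard 6660 px micrograph space into 256 x 256 units
(unit size 26.015625 px) by exact integer counting. Somas share the gridding
implementation under their own provenance tag.

## Carrying densities between spaces

Deformation fields are defined on the *output* grid and map output
coordinates to input coordinates (pull-back). `transfer_ddm` resamples the
input bilinearly and multiplies by the Jacobian determinant of that map, so
integrated counts are conserved by the change-of-variables formula — this is
also how the package resolves the forward-versus-inverse Jacobian ambiguity:
compensation is *defined* by the verifiable conservation property. Each
output cell averages the compensated pull-back over 3x3 quadrature
subpoints; plain cell-center sampling is available (`supersample = 1`) but
the composite rule keeps mass errors well under 1% for curved fields. The
identity map is special-cased to exact pass-through. A test-only
particle-pushing oracle (subdivided cell masses pushed through the
numerically inverted map and deposited with cloud-in-cell weights) checks
the transfer within 2% total variation on random smooth fields.

Synthetic registration fields (`make_deformation`) are sums of low-frequency
sinusoids with analytically evaluated Jacobians, standing in for both the 2D
slice-wise and the 3D block-to-DTI registration steps of a real study;
fields whose minimum determinant reaches 0.2 are rejected as unsafe to
invert. The 2D landmark step itself is implemented: a classic thin-plate
spline (affine part plus r^2 log r radial basis, optional regularization)
with analytic Jacobian, satisfying exact landmark interpolation at zero
regularization and exact affine reproduction.

Projection of gray-matter densities (somas) onto the interface adds each
voxel's density to its nearest interface voxel, ties broken by the smallest
linear voxel index for determinism; fiber centroid DDMs are assigned to
interface voxels by (x, y) column, matching their definition as counts *on*
the WGM boundary.

## Statistics

Regional totals N_B (fibers), N_D (streamlines), N_S (somas), N_T
(streamline terminals) feed: a linear fit of N_D on N_B whose intercept is
tested against zero by its 95% t confidence interval, refitting through the
origin when zero is covered (a scale-relative tolerance of `1e-8 * sd(y)`
guards the degenerate perfect-fit case where the CI has floating-point
width); Pearson and Spearman correlations (average ranks for ties; two-sided
p by the t transform, exact permutation enumeration optional for n <= 7);
Spearman on the strongest connections (either N_B > 100 or the k largest);
voxelwise Pearson within each ROI's interface voxels; false negatives
(N_B > 0, N_D = 0) and false positives (N_B = 0, N_D > 0); sensitivity (the
fraction of ROI-reaching streamlines that reach true positive ROIs); and a
one-way ANOVA of voxelwise correlations across seed depths. Zero-variance
inputs yield an undefined coefficient flagged with the sentinel p = 1; no
multiple-testing correction is applied anywhere. Correlations are computed
with base R's `cor`/`lm` machinery; the test suite verifies them against
direct definitional implementations at 1e-12.

## The orchestrated experiment and problem sizes

`run_experiment()` chains everything: phantom, DWI simulation (SNR 25),
tensor fit, ground-truth fiber/soma generation, DDM gridding, two
Jacobian-compensated 2D transfers (micrograph-to-block and block-to-DTI
stand-ins, amplitudes 1.5 and 1.0 DDM cells), interface assignment or
projection, both trackers across d_w in {0, 0.3, 0.6} mm, and the
comparison tables, written as TSV plus a markdown report laid out like a
correlation table with seed depths in columns. A single master seed
deterministically derives each stage's seed, so the whole report is
reproducible from one integer; repeated runs are byte-identical. Stage
caching (off by default) keys heavy stages on a hash of their upstream
configuration.

Problem sizes are chosen to keep a full experiment around a minute on one
CPU: the default probabilistic sample count is 100 per seed voxel rather
than the emulated tool's 10000 (pass `tracking_params("prob")` for the full
setting — the contract, not the sample count, is what the package tests),
and the test-suite micrographs are 1024^2 px with object sizes scaled
accordingly. The `pipeline_cli` surface is the functions plus a thin
`inst/scripts/run_experiment.R` wrapper.

## What passing tests do and do not show

The phantom is deliberately idealized: flat interface (no folding), piecewise
prolate tensors, single-shell acquisition, no eddy/motion artifacts, uniform
tracer labeling (axon counts fully observed — labeling efficiency of real
tracers is unknown), and a single crossing configuration. Passing the suite
shows the pipeline's bookkeeping is right — conservation at every stage,
geometric fidelity of tracking, correctness of the statistics — and that the
method reproduces the qualitative phenomena it was designed to measure
(partial-volume false negatives cured by deeper seeding; correlation
dominated by strong connections; rank instability among weak connections).
It does not show that any particular correlation value generalizes to real
brains: those numbers depend on anatomy, acquisition and registration error
in ways the phantom does not model.

## Known limitations

* FACT voxel-transit assigns one direction per voxel; sub-voxel bundle
  geometry (caliber below one voxel) is not traversable by construction.
* The probabilistic sampler has no fiber-orientation posterior; its
  uncertainty scale is a free parameter, not estimated from data.
* `transfer_ddm` assumes the pull-back field covers the output support;
  densities mapped outside the input grid are dropped (mass is monitored).
* The voxelwise comparison inherits the DDM cell/voxel aggregation; its
  correlations are meaningful only for ROIs with enough interface voxels.
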