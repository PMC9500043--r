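---
title: "CT-based spatial normalization and regional quantification of mouse brain PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-based spatial normalization and regional quantification of mouse brain PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfpet)
```

## The problem

Quantitative small-animal PET needs every subject's brain in one standard
space before regional uptake can be compared across animals or time points.
The reference anatomical space for the mouse is the Allen Common Coordinate
Framework (CCFv3), with its hierarchical structure ontology and annotation
volume. The gold-standard route into that space runs through a
high-resolution 3-D MR scan per animal, but an MR session per PET-CT
session is slow, costly, and often ethically impossible under repeated
anaesthesia. `ccfpet` implements the alternative: spatial normalization
driven entirely by the CT that every PET-CT session already contains —
skull and soft-tissue contrast substitute for cortical detail — together
with the machinery to build the templates, to quantify how much the CT
route disagrees with the MR route, and to run the downstream regional
statistics.

The package has five functional layers, each usable on its own:

* **imgrid** (`read_volume()`, `resample()`, `embed_in_box()`) — NIfTI/NRRD
  I/O on physical grids. All volumes are canonicalized on load to a fixed
  right-handed (AP, DV, ML) axis order so CCF coordinates are quotable;
  voxel indexing is 0-based with the world coordinate at the voxel centre.
* **atlas** (`load_ontology()`, `build_label_atlas()`) — VOI atlas
  construction from a hierarchical ontology: per VOI the full descendant
  structure set, split at the mid-sagittal plane for bilateral regions,
  then a one-voxel morphological erosion, with a 1.5 mm^3 minimum-volume
  rule (large compared to PET resolution).
* **registration** (`register_rigid()`, `register_elastic()`) — the
  deterministic computational core.
* **templates and validation** (`build_stage1_mean()`,
  `build_final_templates()`, `normalize_subject_ct()`,
  `validate_pipelines()`) — two-stage template construction and the RMS
  displacement comparison of the CT-based against the MR-based pipeline.
* **quantification** (`to_suv()`, `scale_to_global_mean()`,
  `analyze_cohort()`) — SUV conversion, cerebral global-mean scaling,
  paired t tests and Benjamini-Hochberg FDR.

## The registration model

Both engines estimate a mapping from template-space points $x'$ to
subject-space points and are fully deterministic (fixed initialization at
the identity, no random restarts, no stochastic sampling), so identical
inputs and settings reproduce bit-identical transforms.

**Rigid stage.** $\phi(x) = R\,(x - c) + c + t$ with Euler angles applied
about the canonical axes and $c$ the fixed-volume centre. The metric is
the mean squared intensity difference (SSD) within a modality, or negative
mutual information (MI, 32-bin joint histogram with Parzen smoothing) for
cross-modality initialization; SSD is optimized by BFGS with a restart at
the finest pyramid level, MI by a Nelder-Mead simplex. MI is deliberately
restricted to the rigid stage.

**Elastic stage.** Each displacement component is expanded in a separable
3-D cosine (DCT-II) basis over the fixed image's bounding box:
$d_a(x') = \sum_{k} c_{a,k}\, \prod_{j} \cos(\pi k_j u_j)$, with $u_j$ the
normalized position along axis $j$. Because the basis is defined on the
box rather than the voxel lattice, the same coefficients evaluate
consistently at any resolution, which is what makes coarse-to-fine
optimization and cross-resolution field comparison exact. The objective is

$$\frac{1}{N}\sum_{x'} \big(s\,M(\phi(x' + d(x'))) - F(x')\big)^2
  \;+\; \lambda \sum_{a,k} w_k c_{a,k}^2,$$

an SSD data term (images internally normalized to unit scale, $s$ an
optional global intensity factor updated in closed form) plus a bending
energy expressed analytically in coefficient space,
$w_k = \lVert\omega_k\rVert^4$ with $\omega_{k,j} = \pi k_j / L_j$ in
mm^-1; the zero-frequency (bulk shift) terms carry no penalty. Gauss-Newton
with Levenberg damping and step rejection makes the accepted-step objective
non-increasing by construction; divergence is therefore impossible and
non-convergence is reported through the per-level objective traces.

Key tunables in `registration_settings()`:

| parameter | default | meaning |
|---|---|---|
| `basis_orders` | 5 x 4 x 5 | cosine frequencies per axis; on the 16.1 x 9.6 x 12.1 mm working box the shortest representable half-wavelength is ~2-4 mm, matching the smooth inter-subject anatomy differences of the mouse head |
| `regularization_weight` | 1e-4 | bending-energy weight against the unit-scale data term; calibrated on the phantom so that in-span deformations are recovered without oscillation |
| `pyramid_mm` | 0.8, 0.4 | pyramid level spacings; the finest level at 0.4 mm keeps the normal-equation size small while the basis cap on field frequency makes finer sampling unnecessary |
| `max_iterations` | 20 | Gauss-Newton iterations per level |
| `mask` | `"none"` | `"fixed"` restricts the data term to the fixed image's support (recommended: the background carries no information and costs time) |

The total normalization returned by `normalize_subject_ct()` /
`normalize_subject_mr()` is the composition
$x' \mapsto \hat R(x' + \hat d(x'))$, stored as a dense field on the
template grid (`compose_fields()`).

## The VOI atlas

`build_label_atlas()` applies the spec table in order; a voxel already
labelled is never relabelled, and any overlap is reported — overlapping
descendant unions indicate a spec error, not a tie to be broken silently.
The hemisphere split uses the mid-plane of the ML axis: with an even ML
dimension the plane falls between the two central voxel columns; with an
odd dimension the central column belongs to neither side. Erosion uses the
6-connected (face-neighbour) cross, the minimal "one voxel" structuring
element, which spares thin cortical VOIs; a 26-connected cube is available
(`connectivity = 26`) and erodes strictly more. Whether erosion runs
before or after the hemisphere split is a genuine ambiguity; the package
splits first and erodes each side, so the erosion also separates the two
hemispheric halves along the midline. Region volumes therefore shift by a
few percent under the alternative element or ordering, and volume
comparisons against other implementations should carry a matching
tolerance. The default spec table (12 bilateral + 3 central entries,
shipped as `inst/extdata/voi_spec_ccf.csv`) maps the standard
grey-matter divisions to ontology acronyms, with the hindbrain defined as
pons plus medulla; it is an editable file, not code, because name-to-id
grouping is a curation decision.

## The synthetic phantom

Every quantitative claim in the test suite is computed on
`make_reference_anatomy()` / `make_subject()` output, so what the phantom
does and does not emulate bounds what the tests show.

The reference anatomy is a brain ellipsoid (semi-axes 5.6 x 3.1 x 4.4 mm,
inside the native 13.2 x 8.0 x 11.4 mm box) partitioned into 27
mirror-symmetric Voronoi regions around anatomically arranged seeds, each
region a two-leaf subtree of a synthetic CCF-style ontology
(`phantom_ontology()`), wrapped in a 0.4 mm skull shell and extra-cerebral
soft tissue inside the extended 16.1 x 9.6 x 12.1 mm head box — CT needs
structure outside the brain, which is the reason the extended box exists.
Modalities emulate the acquisition geometry of a small-animal PET-CT plus
high-field MR study: CT at 0.2 mm with bright bone and additive Gaussian
noise; MR at 0.15 mm with per-region soft-tissue contrast and dark bone;
PET at 0.4 mm as per-region uptake convolved with a 0.8 mm FWHM isotropic
Gaussian PSF (sub-millimetre scanner resolution) plus Gaussian noise with
variance proportional to intensity — a post-reconstruction surrogate for
count statistics, appropriate because the toolbox consumes reconstructed
images. Subjects are generated by drawing a bounded rigid pose (up to
0.5 mm / 3 degrees) and a random low-order cosine field rescaled so the
maximum displacement equals the requested amplitude; the default 0.5 mm
amplitude matches the scale of displacement the validation study design
targets. Intensity scenes are warped continuously (trilinear), giving
partial-volume edges as a scanner produces; the warped label volume is
kept alongside as the subject-space ground truth.

What the phantom does **not** emulate: attenuation, scatter and
reconstruction artifacts; intensity inhomogeneity and modality-specific
geometric distortion; anatomy outside the ellipsoid topology (no ears,
jaw, airways); and — importantly for the pipeline comparison — any
geometric disagreement between a subject's CT and MR, which share one
ground-truth mapping by construction. Pipeline-agreement numbers measured
on the phantom are therefore an optimistic bound relative to real animals,
where cross-modality distortion adds a floor; the package's role is to
verify that the machinery itself does not introduce disagreement beyond
the half-millimetre regime that matters at PET resolution.

## Statistics stage

PET images are converted to SUV
(`concentration / (activity / weight)`, 1 g/mL tissue assumed — the
assumption cancels under scaling, which a test verifies numerically),
scaled by the cerebral global mean over the union of all atlas labels (the
only brain definition the toolbox owns), averaged per VOI, and compared
with a paired two-tailed Student's t test; two-tailed is the reporting
convention even for directional hypotheses, and a one-tailed switch is
exposed. Benjamini-Hochberg step-up FDR runs across the region set at
q = 0.05. A worked fixture of regional p-values from a published MPTP
test-retest TSPO study (27 regions under this atlas layout, 19 under a
legacy macro-region template) ships in `inst/extdata/mptp_pvalues.csv`;
at q = 0.05 it yields 6 and 3 FDR survivors from 11 and 4 unadjusted
rejections, which the acceptance tests reproduce.

One behaviour worth knowing: global-mean scaling couples regions. A strong
focal increase raises the global mean, so unaffected regions' scaled
values decrease; with the phantom's small residual variance these induced
decreases can themselves reach significance. That is a property of
global-mean normalization, not a defect of the implementation, and it is
the reason reference-region approaches exist (out of scope here).

## Numerical choices and degenerate inputs

* Out-of-field image samples take fill value 0 (air/PET void) for every
  modality; displacement fields extrapolate by edge clamping instead, so
  composition and inversion stay well behaved at the box border.
* `embed_in_box()` centres the volume with any odd one-voxel remainder on
  the high-index side, and refuses to resample — padding conserves the
  value sum exactly.
* NIfTI-1 headers store geometry as 32-bit floats; round-trip tests
  therefore assert spacing/origin to 1e-6 mm, not bit-exactness.
* Degenerate statistics inputs are explicit: zero-variance differences
  give t = 0, p = 1 (zero mean) or p = 0 with a `degenerate` flag;
  all-zero images raise a registration-failure error rather than optimize
  noise; a manifest with more or fewer than two conditions is refused.
* Field inversion (`invert_field()`) is a fixed-point iteration, adequate
  for the smooth sub-millimetre fields used here; it is a test utility,
  not a general diffeomorphism inverter.

## Problem sizes used by the tests

The shipped suite runs the full-resolution phantom (0.2 mm CT, 0.15 mm MR,
0.4 mm PET) for every accuracy claim: rigid pose recovery, in-span elastic
recovery, CT-pipeline ground-truth recovery, and the n = 6 dual-pipeline
agreement study at 0.5 mm deformation amplitude. Replicate-heavy
statistical checks (50 effect-recovery and 200 null cohorts, n = 6 pairs
each) run on a 0.4 mm phantom with identity subject transforms: the
property under test — paired t / FDR behaviour of regional means — does
not depend on registration, and re-registering 250 cohorts would add
nothing but runtime. Template-construction tests likewise use the 0.4 mm
phantom, where registration accuracy is not the assertion.

## Known limitations

* The elastic model is small-deformation and low-frequency by design; it
  cannot represent sliding, topology change, or sharp local deformation,
  and `compose_fields()` does not enforce invertibility.
* MI rigid registration is histogram-limited to roughly a third of a
  degree on the clean phantom; cross-modality initialization below that
  needs a finer pyramid level (`pyramid_mm = c(0.8, 0.4, 0.25)`).
* The atlas volume targets published for the real CCFv3 annotation cannot
  be checked without the Allen distribution files; the atlas machinery is
  validated on the synthetic ontology/annotation with known ground truth
  instead, and `build-atlas` accepts the real files when present.
* Group-level template construction is two-stage by design (multimodal to
  the reference, then intra-modality to the stage-1 mean); no further
  iteration and no unbiased groupwise scheme.
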