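---
title: "Phantom-based analysis of occupation-ratio bias in supraspinatus volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based analysis of occupation-ratio bias in supraspinatus volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbias)
```

## What the package models

Clinical grading of supraspinatus (SSP) atrophy relies on the occupation
ratio (OR): the quotient of the muscle and fossa cross-sectional areas on
the single Y-view slice. True 3D volumetry integrates traced areas over
the whole paracoronal slice stack. The package's scientific claim — which
it demonstrates constructively on voxel phantoms — is that these two
measures diverge specifically in full-thickness tendon tears, because the
retracted muscle belly slides medially away from the bony-landmark-fixed
Y-view plane. The OR then falls without any corresponding loss of volume,
i.e. the single-slice method overestimates atrophy.

Everything is simulated on binary voxel masks; there is no MR signal
model. The pipeline is: phantom generation → slice-wise measurement →
OR/staging → cohort statistics.

## The spindle phantom and its exact volume

Muscles are solids of revolution about the medial–lateral (x) axis with
radius profile

$$ r(x) = R \left(1 - \left(\tfrac{2x}{L}\right)^2\right)^p,
   \qquad x \in [-L/2,\, L/2], $$

with belly radius $R$ (mm), length $L$ (mm) and taper exponent $p > 0$
(default 1, a paraboloid-like fusiform taper). The closed-form volume

$$ V = \pi R^2 \tfrac{L}{2}\, B\!\left(\tfrac12,\, 2p + 1\right) $$

is exact, so every phantom carries its own ground truth — the digital
replacement for water-displacement volumetry of physical specimens. Given
a target volume, `spindle_spec()` solves $R$ and $L$ at a fixed aspect
ratio (length/diameter, default 3, a typical fusiform proportion), so the
analytic volume *equals* the target by construction.

**Voxelization rule.** A voxel belongs to the phantom iff its centre lies
inside the continuous surface — the simplest unambiguous rule. Its error
is first-order in the spacing and oscillates for individual shapes (a
coarser grid can occasionally beat a finer one for one particular
volume), but the mean error across the 10–100 cm³ decade halves reliably
with each halving of the spacing (about 1.6% at 4 mm isotropic, 0.4% at
2 mm, 0.1% at 1 mm); the test suite asserts exactly this averaged
statement. At the default acquisition geometry (below) every specimen in
the decade is recovered to within 2%.

## Grid and measurement conventions

The default grid mimics the acquisition geometry of a 3 T shoulder
protocol: 0.52 mm in-plane (a 200 mm field of view at a 384 matrix) and
3 mm slices with a 0.3 mm gap stacked along the anterior–posterior axis,
so the slab pitch is 3.3 mm. Axes are x = medial→lateral,
y = anterior→posterior, z = inferior→superior; volumetry slices
perpendicular to y (paracoronal), the Y-view is a constant-x
(oblique-sagittal) plane.

* **Area** is foreground-pixel count × pixel area. This matches
  rasterized manual tracing; sub-pixel polygon area would be more
  accurate for smooth shapes but would no longer correspond to what
  tracing software integrates.
* **Long axis** is the maximum Feret diameter of the pixel-corner
  boundary polygon (computed on its convex hull; ties in direction are
  broken towards the smallest angle to the x-axis for determinism).
  **Short axis** is the caliper extent of the whole region perpendicular
  to the long-axis direction — the standard lesion-measurement (RECIST)
  convention; the short segment need not cross the long one. The corner
  convention makes a single pixel measure $\sqrt2$ px and inflates a
  digitized disk's Feret diameter by up to about one pixel diagonal;
  closed-form comparisons in the tests use that as the stated tolerance.
  The cross-product CP = long × short then satisfies CP ≥ area for
  convex regions and CP/area → 4/π for a disk.
* **Volume** is $V = \sum_i A_i (t + g)$ in cm³. The gap belongs in the
  pitch because each traced slice stands for a slab of thickness plus
  gap of tissue; integrating with bare thickness is available via
  `gap_mm = 0` for sensitivity analyses.
* **OR** is always the quotient of traced *areas*; CP-based ratios are
  emitted as an auxiliary column only, since the ratio definition is an
  area quotient and the CPs are a derived convenience measurement.
* **Thomazeau boundaries** are upper-bound inclusive: OR = 0.60 is stage
  I, OR = 0.40 is stage II ("below 0.40" being stage III forces 0.40
  into stage II; the same convention is applied at 0.60).
* **Ellman grading**: depth < 3 mm → I, 3–6 mm (closed) → II,
  > 6 mm → III; by fraction of tendon diameter, < 1/4 → I,
  [1/4, 1/2) → II, ≥ 1/2 → III. A fraction of exactly one half is not
  assigned by the classical wording; the package sends it to the more
  severe grade. When depth and fraction disagree, depth (the primary
  criterion) wins.

## The shoulder phantom: fossa, Y-view, retraction

The fossa is the static bony container. It is built from a *basis*
spindle — the subject's nominal, pre-atrophy muscle — swept medially
through the retraction range and dilated by a ball of radius
`fossa_margin_mm` (default 1.5 mm). Sweeping before dilating guarantees
the muscle stays inside the fossa at every retraction; because the sweep
only extends the medial side, the lateral fossa (where the Y-view sits)
is unaffected by it. Basing the fossa on the *nominal* rather than the
actual muscle is essential: atrophy must shrink the muscle inside an
unchanged fossa, or the OR could never express it.

The Y-view has no bony landmarks in a phantom, so it is parametric: the
constant-x plane `yview_offset_mm` (default 22 mm) medial to the most
lateral fossa-containing slice. With the default geometry this puts an
intact, non-atrophied muscle at OR ≈ 0.75, matching the upper end of
reported intact values.

Retraction is a rigid medial translation of the muscle only, quantized
to whole voxels along x. Quantization makes the conservation property
exact — the voxel-count volume is bit-identical across a retraction
sweep — and isolates the medialization mechanism from any shape change.
Partial-thickness defects scale the radius in the lateral 10% of the
muscle length by one minus the tear fraction: tendon-end damage without
belly medialization, consistent with the observation that the OR still
tracks volume in partial tears.

## The synthetic cohort

`cohort_spec()` fixes the study conditions: 39 intact / 75 partial / 35
full-thickness subjects, Ellman grade counts 45/19/11 among partial
tears and Patte grade counts 19/10/6 among full-thickness tears (drawn
as exact multisets so classification round-trips exactly). Per subject:

* **Nominal volume**: lognormal, median 62 cm³, sdlog 0.10. The sdlog
  captures moderate inter-person scapula/muscle size variation; the
  median is set so the intact group mean lands near 57 cm³.
* **Atrophy/occupation factor** (scales volume linearly; radius by its
  square root, length preserved): truncated normal per group —
  intact 0.93 ± 0.15 on [0.50, 1.10], partial 0.74 ± 0.16 on
  [0.35, 1.05], full 0.55 ± 0.10 on [0.30, 0.85]. The group means
  reproduce reported mean volumes (≈ 57/44/31 cm³ against published
  56.9/43.6/31.1); the spreads are wide because reported per-group OR
  ranges are wide (intact 0.49–0.89), i.e. muscle bulk varies more
  within a clinical group than body size does. These spreads, not the
  size spread, carry the within-group OR–volume correlation.
* **Belly retraction** (full-thickness only): normal per Patte grade,
  3.5 ± 2 / 9 ± 3 / 16 ± 4 mm, floored at 0.6 mm. These are belly
  displacements, deliberately smaller than stump retractions (the
  tendon stretches before the belly follows). Retraction is drawn
  independently of atrophy, consistent with the reported absence of
  volume differences between Patte subgroups — and this independence is
  precisely what decorrelates OR from volume in the full-thickness
  group.
* **Reader noise**: multiplicative lognormal with σ = 0.05 per reader
  on the measured OR. No noise model is reported for the clinical
  readers; a 5% coefficient of variation is the simplest choice that
  reproduces inter-reader correlations in the low-0.9s.

All parameters were fixed once from these considerations in a design
study before the pipeline tests were written, and are exposed in
`cohort_spec()` rather than hard-coded. Under the defaults the pipeline
yields per-group OR–volume correlations of roughly 0.8/0.86/0.2
(intact/partial/full) — the clinical pattern (reported 0.84/0.93/0.68)
in exaggerated form: the idealized phantom has a steeper lateral taper
and no compensating anatomy, so retraction bites harder than in vivo.
The package therefore treats the *ordering* (full-thickness lowest,
bias positive) as the reproducible claim, not the numerical r values.

## What the generator does not emulate

No MR contrast, bias fields, or partial-volume effects; no fatty
infiltration (atrophy is purely geometric); no anatomically shaped
scapula, so Y-view localization is parametric rather than
landmark-driven; no slices medial to the Y-view are evaluated; muscle
cross-sections are circular, and real fossa/muscle shapes are not. A
passing cohort test shows the *mechanism* is sufficient to produce the
bias pattern — not that the generator's magnitudes transfer to patients.

## Numerical and reporting choices

* Printed percentages round half away from zero to one decimal
  (`round_half_up()`), matching clinical-report style; full precision is
  retained internally. The worked-example overestimation follows the
  printed chain (54.7 − 47.2 = 7.5; 7.5/54.7 = 13.7%), which differs in
  the last digit from the full-precision ratio (13.6%) — the report
  convention is authoritative for printed output, and `tidy()` exposes
  both.
* The overestimation statistic uses group means, not per-subject
  ratios, matching the published arithmetic.
* NIfTI headers store spacing as single floats; round-trips preserve
  voxel data exactly and spacing to float precision (~1e-7 relative).
* Degenerate inputs fail loudly: empty slices cannot be measured for
  axes, a zero fossa area raises a division error naming the slice, and
  correlation of constant vectors is refused rather than returned as
  `NA`.
* Pearson, ANOVA and Bonferroni adjustment are delegated to R's
  standard routines (`stats::cor`, `stats::aov`,
  `stats::pairwise.t.test`); the package adds validation and tidy
  accessors, and its tests pin the contracts (bounds, affine
  invariance, the cap at 1).

## Problem sizes

The bundled experiments are sized for interactive use: ten phantoms of
10–100 cm³ at the 0.52/3.3 mm acquisition grid for the ex vivo run
(≈ 1 s), and the full 149-subject cohort at the same grid (≈ 8 s on one
core). The discretization study in the tests spans 4 mm down to 1 mm
isotropic grids. Finer grids improve accuracy roughly linearly in the
spacing and cost cubically; the defaults keep single-specimen error
well under the 2% level relevant to the validation claim.

## Limitations

The phantom's circular cross-sections make the OR of an intact subject
depend only on the radius quotient at the Y-view; real fossa occupancy
geometry is richer. Retraction magnitudes for the belly are plausible
but not measured quantities. The simulated overestimation (≈ 40% under
defaults) is therefore an upper-bound illustration of the mechanism,
not an estimate of the clinical 13.7%. Finally, the OR staging
boundaries are applied to noisy measured ORs, so stage counts near a
boundary are sensitive to the reader-noise σ.
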