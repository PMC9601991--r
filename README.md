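# orbias

Slice-wise muscle volumetry and occupation-ratio bias analysis for the
supraspinatus.

## The problem

Supraspinatus (SSP) muscle atrophy guides the decision whether a torn
rotator cuff is worth repairing. Because clinical MRI rarely covers the
whole muscle, atrophy is usually graded from a **single** oblique-sagittal
slice — the *Y-view* — via the **occupation ratio**

```
OR = A_muscle / A_fossa
```

the quotient of the muscle's cross-sectional area and the supraspinatus
fossa area on that slice, staged after Thomazeau
(I: OR ≥ 0.60, II: 0.40 ≤ OR < 0.60, III: OR < 0.40). True 3D volumetry
instead integrates traced areas over the whole slice stack
(Cavalieri/slab-stack estimation with the interslice gap in the pitch):

```
V = Σᵢ Aᵢ · (t + g)        t = slice thickness, g = interslice gap
```

In full-thickness tendon tears the whole myotendinous unit retracts
medially. The Y-view plane, anchored to bony landmarks, does not move with
it — so the single-slice muscle area falls for a reason that has nothing
to do with volume loss, and the OR **overstates atrophy**. `orbias`
quantifies that bias: the group-level overestimation statistic

```
rv = V̄_full / V̄_intact      (relative volume preserved)
rs = S̄_full / S̄_intact      (relative Y-view surface preserved)
overestimation = (rv − rs) / rv
```

and a voxel-phantom simulation framework that reproduces the mechanism
end to end: spindle-shaped muscles with exactly known (closed-form)
volumes, a static fossa envelope, parametric atrophy and medial
retraction, tear staging after Ellman (partial, by depth) and Patte
(full-thickness, by stump position), reader-noise simulation, and the
cohort statistics (Pearson correlations, one-way ANOVA with Bonferroni
post hoc) to analyse it all. It is aimed at musculoskeletal imaging
researchers who want to study — or teach — what single-slice morphometry
can and cannot see.

## Worked example

The headline statistic from published group means (intact 56.9 cm³,
full-thickness 31.1 cm³, Y-view surface ratio 47.2%):

```r
library(orbias)
ov <- overestimation(56.9, 31.1, 1, 0.472)
ov
#> Relative volume preserved: 54.7%; relative Y-view surface preserved: 47.2%
#> Surface deficit beyond volume loss: 7.5 percentage points (13.7% of the volume ratio)
```

So the single-slice method reports 7.5 percentage points more atrophy
than the volume actually lost — a 13.7% relative overestimation.

Validating the volumetry itself on ten phantoms with exactly known
volumes (10–100 cm³, 0.52 mm in-plane, 3.3 mm slab pitch):

```r
glance(run_exvivo())
#> # A tibble: 1 × 4
#>   n_specimens     r max_abs_error_pct slice_spacing_mm
#>         <int> <dbl>             <dbl>            <dbl>
#> 1          10 1.000              1.63               3.3
```

Every phantom is recovered to within 1.7% and the true/measured
correlation is ≈ 1: slab-stack integration is a faithful volume
standard. The mechanism, isolated on one 57 cm³ phantom:

```r
retraction_sweep(spindle_spec(57), c(0, 6.6, 13.2))
#> # A tibble: 3 × 5
#>   retraction_mm volume_cm3 or_value muscle_area_mm2 fossa_area_mm2
#> 1           0         56.8    0.741           412.            556.
#> 2           6.6       56.8    0.426           237.            556.
#> 3          13.2       56.8    0.173            96.1           556.
```

The voxel-count volume is bit-identical across the sweep (retraction is
a whole-voxel rigid translation) while the OR collapses from 0.74 to
0.17 — pure medialization bias. A full synthetic cohort
(39 intact / 75 partial / 35 full-thickness) is one call:

```r
res <- run_cohort(seed = 1)
glance(res)      # per-group OR-volume correlations, inter-reader r, bias
autoplot(res)    # OR vs volume scatter by group
```

The OR tracks the 3D volume well in intact shoulders and partial tears
but decouples in the full-thickness group, where retraction varies
independently of volume — the package's reproduction of the clinical
finding.

## Command line

A thin CLI ships in `exec/orbias` with one verb per pipeline stage
(`phantom`, `volume`, `or`, `stage`) plus the two experiment drivers
(`exvivo`, `cohort`), e.g.

```sh
orbias phantom --volume 50 --out mask.nii.gz
orbias volume mask.nii.gz --axis y --thickness 3 --gap 0.3
orbias cohort --seed 1 --out results/
```

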