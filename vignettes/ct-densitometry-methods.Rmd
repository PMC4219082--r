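---
title: "Methods: automated CT densitometry and the Cerebral Edema Score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CT densitometry and the Cerebral Edema Score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctces)
```

## The model

Unenhanced brain CT expresses tissue density in Hounsfield Units: water is
0, air about −1000, cranial bone far above 100. The intracranial
compartment — parenchyma, CSF, blood — occupies 0–79 HU, and cerebral edema
lowers parenchymal attenuation towards the upper CSF range. The package's
central quantity is therefore a *band proportion*: for a CT image, λ_p is
the percentage of retained intracranial pixels at HU = λ (so the 80 values
sum to 100); an examination of *n* images is summarised per HU by the
unweighted mean (1/n)Σ_k λ_p^k, and

$$\mathrm{HU}_\alpha^\beta \;=\; \frac{1}{n}\sum_{k=1}^n\sum_{\lambda=\alpha}^{\beta}\lambda_p^k$$

with both band ends inclusive. The Cerebral Edema Score is
CES = HU₁₇²⁴ and the mortality score mCES = HU₁₉²³; nesting of the bands
guarantees mCES ≤ CES. The score is a *proportion*, not a count, which
makes it insensitive to head size and to the number of slices.

Everything else in the package exists to make that quantity trustworthy:
the six-stage artifact elimination guarantees that only intracranial pixels
enter λ_p, and the cohort statistics locate which band discriminates two
groups and where to cut a score.

## Assumptions

* The cranium forms a closed, roughly left–right symmetric shell of
  high-attenuation bone around a single connected interior. Fractures and
  craniotomies may open it; the sealing stages restore a closed curve.
* Intracranial pixels of interest lie in 0–79 HU. Anything outside — air
  cells, calcifications, metal — is an artifact by definition and is
  dropped by the boundary condition, not by geometry.
* Series averaging weights every image equally, following the averaged-
  proportion formula; a pooled-pixel alternative (weighting images by
  retained pixel count) is available via `series_distribution(method =
  "pooled")` for sensitivity analysis, because the two differ when interior
  area varies strongly along the stack.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bone_threshold` | 150 | HU | well above the 0–79 tissue range, well below metal; shell detection is insensitive to ±50 |
| `ray_count` | 720 | rays | 0.5° angular resolution for gap detection |
| `max_gap_deg` | 15 | degrees | gaps up to this width are fractures, bridged locally; wider ones are craniotomy-scale and sealed by mirror symmetry. The boundary is a free design choice: typical linear fractures subtend a few degrees, craniotomy flaps tens |
| `min_interior_px` | 100 | pixels | vertex slices with tiny interiors give unstable proportions and are excluded from series averages |
| `hu_lo`, `hu_hi` | 0, 79 | HU | the intracranial boundary condition |
| CES band / cutoff | 17–24 / 16.03 % | HU / % | severity operating point; 22.58 % has also circulated for the same sensitivity/specificity pair and is selectable, but the package defaults to 16.03 |
| delayed cutoff | 16.29 % | % | delayed-edema screening operating point |
| mCES band / cutoff | 19–23 / 15.27 % | HU / % | mortality operating point |
| `alpha` | 0.05 | — | per-bin significance level; no multiplicity correction by default (Holm available), matching the per-bin reporting style the scores originate from |

## Numerical choices

* **HU are integers.** DICOM rescale results are rounded half-away-from-zero;
  the binning is by integer HU, so ties in rescaled values are impossible by
  construction.
* **Connectivity.** Component labelling is 8-connected (a diagonally touching
  shell stays one object); flood fills are 4-connected (they cannot leak
  through a diagonal joint). This asymmetry is deliberate: it is the
  conservative pairing for a thin closed curve.
* **Shell center.** An open shell's pixel centroid is biased away from the
  missing arc, which would skew the mirror axes. The center is instead
  refined by averaging midpoints of diameters whose two first-hit points both
  exist — an estimator that is exact for a symmetric shell and converges
  linearly; iteration stops at 0.05 px.
* **Gap sealing.** Fracture bridges interpolate the first-hit radius across
  the gap and are rasterised 3 px thick with 3× angular supersampling.
  Pinhole gaps narrower than the ray resolution are plugged by morphological
  closing (3–7 px boxes) applied only when the shell tests open, so clean
  phantoms are untouched and segmentation of an intact phantom is exact.
  Mirror sources within 2 rays of a defect edge are rejected (grazing rays
  report unreliable radii); if both the vertical and horizontal mirror of a
  defect ray are open, the cranium is declared unsealable — by construction
  mirror-symmetric double defects cannot be repaired from symmetry.
* **Cutoff selection.** "Highest predictive power" is operationalised as
  Youden's J, with ties broken towards higher specificity and then the lower
  cutoff; ordering keys are rounded at 1e-9 so floating-point noise cannot
  defeat the tie-breaks. A closest-to-corner criterion is available.
* **Exactness switch.** Mann–Whitney uses the exact null distribution for
  combined n ≤ 12 without ties, the tie-corrected normal approximation with
  continuity correction otherwise.
* **Serialisation.** Distribution CSVs are written with `%.17g` and parsed
  by the base reader, so on-disk and in-memory analyses see bit-identical
  values — rank tests are sensitive to epsilon-level tie breaking.

## The synthetic generator

`make_phantom()` renders what the elimination algorithm must survive:
elliptical cranial shell (1000 HU), scalp ring (30–60 HU, overlapping brain
attenuation), an interior drawn i.i.d. from a CSF/parenchyma/blood mixture,
fracture gaps, craniotomy arcs, an EVD tract (3000 HU), air bubbles
(−1000 HU) and a border-touching gantry arc. Because interior pixels are
drawn i.i.d. from the mixture, the ground-truth distribution is exact and
segmentation of an artifact-free phantom must reproduce the retained
multiset bit-for-bit — that equality is tested, not approximated.

`simulate_cohort()` works at the distribution level: each subject gets an
expected HU distribution, then multinomial "images" are drawn from it and
averaged exactly as the densitometry module would. This is statistically
equivalent to rendering and perfectly segmenting full image stacks, and it
is what makes 100-cohort calibration studies affordable; `render = TRUE`
additionally rasterises image stacks for end-to-end checks. The default
conditions are 30 mild vs 30 severe subjects, 10 images of 20 000 retained
pixels each.

The mild generator draws parenchyma around 29 HU. The severe generator
adds an *edematous excess component* — a discrete normal centred at the
edematous mode (24 HU), softly truncated to HU 17–24 — worth exactly
`band_mass_shift` (default 8) percentage points of expected band mass; the
blending dilutes all other bins proportionally. Two consequences are
deliberate: the expected CES difference between groups equals the dial
setting exactly, and the severe histogram peak moves from 29 towards 24,
matching the peak separation observed between surviving and deceased
patients. A flat in/out-of-band rescale was rejected: it creates a
discontinuous distribution whose out-of-band dilution, not the band itself,
becomes the strongest group signal.

Between-subject variability mirrors what real cohorts vary in: the
parenchymal mode (sd 0.6 HU) and width (sd 0.4 HU), CSF and blood mixture
weights (lognormal, cv 0.25 and 0.4 — ventricle size and hemorrhage burden
vary widely in TBI), an in-band mass jitter (sd 1.5 pp), and a multiplicative
per-bin roughness (cv 0.2) representing fine-grained textural heterogeneity
that smooth mixtures miss. The dispersion was calibrated, at design time, so
a default cohort reproduces the discriminability scale reported for the
reference cohort (group CES medians near 14 and 22 %, ROC AUC in the
0.9–0.97 range at an 8 pp gap). Delayed-edema and deceased subjects reuse
the severe generator — initial distributions of delayed converters are
described as indistinguishable from overt severe edema, and nothing beyond
that is quantified, so the generator treats the distinction as a label.

Cohorts are drawn from a single seeded stream: per-subject streams seeded
by an arithmetic progression correlate in their first draws (a property of
the Mersenne-Twister seeding) and would break group exchangeability under
the null. Phantom series retain per-slice derived seeds
(`master + 97003·k`), where the draws are high-dimensional and this effect
is negligible.

**What passing tests do and do not show.** The phantoms validate the
geometry and bookkeeping of the pipeline — closure, boundary conditions,
exact proportions — and the cohort simulations validate the statistical
machinery's calibration and power under a known effect. They do not
establish clinical validity of the cutoffs, model beam hardening, partial
volume at the skull base, motion artifacts, or scanner-to-scanner HU
drift; real cohort performance must come from real images.

## Design choices where the field leaves room

* **Discriminative band discovery.** Bands are maximal contiguous runs of
  bins with p < α. The *discovered* band (`primary_band()`) is the run
  containing the most significant bin. A purely width-based choice is
  unstable for proportion data: adding mass to one band necessarily dilutes
  every other bin, and coherent anatomical variability can assemble long,
  weakly significant runs elsewhere; the evidence-strength rule matches how
  a strongest band (smallest p) is singled out in practice.
* **Cranium detection with defects.** A fractured shell is several
  components; the detector keeps every border-free high-HU component at
  shell radius from the estimated center, rather than a single largest
  component, and rejects interior metal by its small radius. For an intact
  shell this reduces to "the largest enclosing component".
* **Mirror axis.** Craniotomy sealing mirrors across the vertical axis
  (anatomical midline) first, falling back to the horizontal axis; the
  pseudo-axisymmetry of the skull is strongest left–right.
* **Rounding of rescaled HU.** Half-away-from-zero, chosen for symmetry
  around the water point; the binning rule is otherwise unstated in the
  field.

## Problem sizes

The shipped tests segment phantoms at 256 px (identical geometry, faster
rasterisation) plus 50 full 512 px phantoms for mask-recovery statistics;
calibration and recovery studies use 100 cohorts of 30/30 subjects each.
These sizes give binomial confidence intervals tight enough to detect a
miscalibrated test (±4 pp on a 5 % rate) and Monte-Carlo error below 0.2 pp
on group CES differences.

## Known limitations

* Sealing assumes one cranium per slice; twins-in-field or severely tilted
  acquisitions are out of scope.
* The gantry rule (border-touching solid components) assumes the head does
  not touch the image border.
* Slices are treated independently; no 3-D regularisation of masks across
  the stack.
* DICOM support covers single-frame, uncompressed little-endian CT images —
  the storage form of conventional axial brain CT; compressed transfer
  syntaxes are rejected with a clear error.
* mCES differs from CES only by HU 18 and 24; with few mortality events the
  distinction is within small-sample variance, and the package treats both
  as reportable scores rather than claiming one is superior.
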