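# ctces — automated brain-CT densitometry and cerebral edema scoring

Cerebral edema is the leading driver of raised intracranial pressure in
pediatric traumatic brain injury, yet its severity on an unenhanced CT scan
is usually judged by eye, from subtle parenchymal hypoattenuation that is
hard to call reliably. `ctces` implements a fully automated, quantitative
alternative: strip everything that is not intracranial tissue from each
axial slice, histogram the remaining Hounsfield-Unit (HU) values, and score
the patient by how much of the intracranial area sits in the narrow
attenuation band that edematous tissue occupies.

The package is aimed at neuroimaging researchers who want a reproducible,
scriptable densitometry pipeline — and at methodologists who want to study
the behaviour of band-proportion scores on synthetic cohorts with known
ground truth.

## The method

**Artifact elimination (six stages).** For each 512×512 axial slice the
pipeline (1) detects the cranial shell by its high attenuation (≥150 HU by
default), (2) removes scanner components (gantry ring, head rest) as solid
structures touching the image border, (3) coordinates the cranial interior
into four quadrants around its centroid, (4) seals fracture gaps (≤15° of
arc) with temporary *pseudo-cranial pixels* bridging the intact shell, (5)
seals craniotomy-scale defects by exploiting the cranium's approximate
left–right mirror symmetry, and (6) flood-fills the sealed interior and
keeps only pixels with 0 ≤ HU ≤ 79 — the range spanned by CSF (≈0–15),
parenchyma (<40) and blood (<80). Scalp is excluded by position even where
its HU overlaps brain tissue; pseudo-cranial pixels never enter any
statistic.

**Densitometry.** For one image, λ_p is the percentage of retained pixels
with HU = λ, so Σ_{λ=0}^{79} λ_p = 100. A series of *n* images is averaged
per HU value, (1/n) Σ_k λ_p^k, and a band proportion is written

    HU_α^β = (1/n) Σ_{k=1}^{n} Σ_{λ=α}^{β} λ_p^k .

**Scores.** The Cerebral Edema Score is CES = HU₁₇²⁴; its mortality variant
is mCES = HU₁₉²³ ⊆ CES. Default operating points: CES ≥ 16.03 % flags
severe edema, CES ≥ 16.29 % flags delayed-edema risk, mCES ≥ 15.27 % flags
mortality risk (ties classify positive).

**Cohort statistics.** A Shapiro–Wilk gate routes to nonparametric tests;
per-HU-bin Mann–Whitney scans locate the discriminative band (maximal
significant run containing the most significant bin); empirical ROC curves
with Youden-J cutoff selection, predictive values, Kruskal–Wallis and
Fisher/chi-square tests complete the pipeline.

**Synthetic phantoms.** `make_phantom()` renders seeded head phantoms —
elliptical cranium, scalp, tissue mixture, fractures, craniotomy arcs, EVD
catheter, air bubble, gantry arc — with exact ground-truth masks, and
`simulate_cohort()` draws labelled mild/severe cohorts whose HU 17–24 mass
differs by a configurable number of percentage points.

## Worked example

```r
library(ctces)

# a fractured, craniotomised phantom with an EVD catheter
spec <- phantom_spec(seed = 11,
                     fractures  = data.frame(angle_deg = 40, width_px = 8),
                     craniotomy = data.frame(start_deg = 60, span_deg = 60),
                     evd = TRUE)
ph  <- make_phantom(spec)
seg <- segment_slice(ph$slice)
dice_coefficient(seg$region_mask, ph$truth$intracranial_mask)
#> [1] 0.9987963

d <- slice_distribution(seg)
score_subject(series_distribution(list(d)), subject_id = "phantom-11")
#> # A tibble: 1 x 6
#>   subject_id   ces  mces verdict_severity verdict_delayed_risk verdict_mortality_risk
#>   <chr>      <dbl> <dbl> <chr>            <chr>                <chr>
#> 1 phantom-11  14.8  9.79 mild             low                  low
```

The Dice coefficient says the recovered intracranial mask overlaps the
ground truth almost perfectly despite the fracture and the missing 60° of
skull. The phantom draws its parenchyma around the healthy mode (29 HU), so
its CES (14.8 %) falls below every cutoff and all three verdicts are
negative.

At cohort level:

```r
co   <- simulate_cohort(cohort_spec(seed = 5))   # 30 mild / 30 severe
scan <- per_bin_scan(co$subjects[31:60, ], co$subjects[1:30, ])
primary_band(scan)
#> # A tibble: 1 x 4
#>      lo    hi width    min_p
#>   <int> <int> <int>    <dbl>
#> 1    18    24     7 2.37e-10

roc <- roc_curve(vapply(co$distributions, compute_ces, numeric(1)),
                 co$manifest$group == "severe")
glance(roc)
#> # A tibble: 1 x 7
#>     auc n_pos n_neg cutoff sensitivity specificity     j
#> 1 0.940    30    30   17.0       0.967       0.800 0.767
```

The scan rediscovers a discriminative band inside HU 17–24, and the
ROC-selected CES cutoff separates the groups with Youden J ≈ 0.77. `autoplot()` methods draw the distribution, scan and
ROC figures.

A command-line wrapper with `segment`, `score`, `compare` and `simulate`
subcommands lives at `inst/cli/ctces.R`.

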