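---
title: "Quantifying tau, amyloid, small vessel disease and white-matter hyperintensity burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tau, amyloid, small vessel disease and white-matter hyperintensity burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhpath)
```

## The measurement problem

White-matter hyperintensities (WMH) — bright lesions on T2-weighted MRI of
ageing brains — have at least two candidate drivers: ischaemic damage from
small vessel disease (SVD) of the white matter, and degeneration secondary to
cortical Alzheimer-type pathology (hyperphosphorylated tau, HPτ, and
amyloid-β, Aβ). Disentangling them requires putting all four quantities on
comparable per-case scales and then asking which ones predict WMH severity
once age is controlled. `wmhpath` implements that chain end to end:

1. **IHC percent-area quantification** (`classify_pixels`,
   `filter_components`, `percent_area`, `aggregate_case`): the fraction of
   cortical area covered by AT8 (HPτ) or 4G8 (Aβ) immunoreactivity.
2. **Vessel morphometry** (`measure_vessel`, `sclerotic_index`,
   `aggregate_si`): the sclerotic index SI = 1 − D~int~/D~ext~ of white-matter
   arterioles as the SVD severity measure.
3. **Lesion rating** (`census_lesions`, `score_region`, `combine_scores`):
   ordinal 0–3 ARWMC-style scores from lesion masks, by maximum caliper
   diameter and confluence.
4. **Cohort statistics** (`pooled_t`, `mann_whitney_u`, `route_test`,
   `partial_corr`, `stepwise_forward`, `chi_square_2x2`): normality-routed
   group contrasts, age-controlled one-tailed partial correlations, and
   forward stepwise regression of WMH scores on the pathology burdens.

Because no raw case data accompany the published design, every stage is
validated on **synthetic inputs with exact ground truth** (`make_ihc_montage`,
`make_vessel_image`, `make_lesion_mask`, `make_cohort`), and `run_pipeline`
exercises the whole chain on a generated 36-case study.

## IHC quantification: model and parameters

A montage is a 3×3 grid of square tiles. The default geometry is 512 px
tiles at 0.85 μm/px, so the montage spans 1305.6 μm on a side and covers
1.70 mm² of tissue. A pixel is immunopositive iff each of R, G, B lies in an
inclusive range:

* AT8 (HPτ): R 25–170, G 27–156, B 11–126;
* 4G8 (Aβ): R 50–180, G 20–168, B 8–139, plus a **minimum component area of
  100 μm²**.

The size filter exists because physiological amyloid precursor protein (APP)
also stains with 4G8 as punctate sub-100 μm² signals; removing components
below the threshold excludes it from the amyloid burden. Components use
**8-connectivity** (diagonal contact joins a blob), the usual convention in
blob quantification; the threshold ranges are read as **inclusive at both
ends** since the published ranges carry no open/closed notation. An optional
ROI-exclusion mask removes white matter and meningeal structures from **both**
numerator and denominator, so percent area always refers to measured cortex.

Per case, 24 locations are sampled: six cortical sections (prefrontal,
midfrontal, entorhinal, temporal, parietal, occipital) × four locations
spanning the sulcus-to-gyral-tip gradient (one sulcus, two midsection, one
gyral tip). The published design states the total (24) and the location
classes but not the per-section split; 4-per-section is this package's
reading and is encoded in `sampling_plan()`. Regional burdens are means over
locations — frontal pools prefrontal+midfrontal, temporal pools
entorhinal+temporal — and the total is the mean of the four regional values.

## The synthetic IHC scenes: what they do and do not emulate

`make_ihc_montage` paints tangles (flame-shaped blobs ~5–10 μm),
neuropil threads (1-px meandering segments 25–80 μm long), plaques (ragged
discs 18–44 μm across) and APP-like specks, with paint colours drawn
uniformly from the *strict interior* of the marker's RGB box and background
from a pale haematoxylin-like palette verified to lie outside the box. The
generator and classifier are therefore **exact duals**: the classified mask
equals the painted mask pixel for pixel, and the reported `true_fraction` is
an exact pixel count, which is what lets the test suite demand exact
(not approximate) recovery. Specks are kept strictly below 100 μm² and
8-disconnected from all other paint so the size filter removes exactly them.

This dual construction deliberately omits real-world nuisances: no staining
gradients, chromogen mixing, out-of-focus blur, or pixels near the threshold
boundary. Passing the duality suite shows the classifier, component filter
and bookkeeping are correct — it says nothing about how well the fixed RGB
boxes segment real slides, which is a property of the published calibration,
not of this code.

When a `target_fraction` is requested the generator adds structures until the
painted fraction reaches it; fractions above 0.35 are refused because denser
packing merges the scene into confluent paint and the per-structure ground
truth stops being meaningful.

## Vessel morphometry

Vessels are rendered as annuli between two *confocal* ellipses (same centre,
orientation and axis ratio), so along every ray through the centre the
internal:external ratio — hence the SI — equals D~int~/D~ext~ exactly,
independent of orientation and eccentricity. `measure_vessel` thresholds the
dark wall (grey < 0.7 by default), then takes internal and external caliper
diameters along three orientations 60° apart through the wall centroid; the
published design measures diameters three times per vessel without stating
the combination rule, and this package takes the **mean of the three
per-orientation SIs** (documented choice; averaging diameters first differs
only at the third decimal for realistic eccentricities). Measured diameters
land within ~1 px of truth (sampling step 0.25 px, +1 px for the extent of
boundary pixels); the tests enforce a 2-px tolerance.

Eligibility follows the ">50 μm" rule applied to the **external** diameter
(the published text does not say which diameter; external is what the
thresholded wall delivers directly). Severity bands are assigned half-open —
SI ≤ 0.3 normal, (0.3, 0.5] mild-to-moderate, > 0.5 severe — because the
published band edges overlap at 0.3 and 0.5.

Aggregation mirrors the sampling design: 8 vessels per white-matter block,
frontal pooling the prefrontal and midfrontal blocks (16 SIs), and the total
SI the mean of the four regional means.

## Lesion rating

`census_lesions` labels 8-connected components and reports each component's
maximum caliper (Feret) diameter. The reported diameter is
`(max centre-to-centre distance + 1 px) × scale`: adding one pixel accounts
for the extent of the boundary pixels and makes the measure stable under
resolution changes (a disc rasterised at 2× resolution with halved scale
keeps its diameter). At the default 4 px/mm the caliper is only good to
~0.25 mm, so lesions *on* the 10 or 20 mm cutoffs are genuinely undecidable
at that resolution — the validation suites therefore compare the rating
against the rule table applied to the *measured* census, and use sizes well
inside each band when asserting absolute scores.

Scores follow the size taxonomy: 0 no lesions; 1 punctate (all components
< 10 mm); 2 early confluent (a component reaching 10–20 mm, **or** a bridged
complex of 10–20 mm lobes); 3 confluent (beyond 20 mm). Two boundary
decisions are the package's own, as the published "<10", "<20", ">20" leave
10 and 20 unassigned: exactly 10 mm and exactly 20 mm both fall in the
early-confluent class, matching the "10–20 mm" phrasing for bridged lesions.
A **bridge** is detected by erosion-split: eroding a component by half the
bridge width (default 3 mm total) removes connections locally thinner than
that; if the component then splits into lobes whose centroids are ≥ 10 mm
apart it is a bridged complex, and — the third documented decision — a
bridged complex whose lobes all stay ≤ 20 mm scores 2 even though the
complex as a whole spans more than 20 mm, since that is precisely the
configuration the taxonomy calls early confluent. Any lobe beyond 20 mm
scores 3.

The parieto-occipital score combines the parietal and occipital regions by
**maximum** (configurable to mean; the published design does not define the
combination), and the total is the mean of frontal, temporal and
parieto-occipital — three values, matching the reported scheme.

## Cohort statistics

* `pooled_t` is the equal-variance two-sample t, usable directly from
  printed means/SDs/ns so published demographic tables can be re-checked;
  with one missing post-mortem-delay case, listwise deletion reproduces the
  df = 33 convention.
* `mann_whitney_u` reports U = min(U₁, U₂) with midrank ties. The p-value is
  an exact enumeration over rank subsets (valid under ties) whenever
  `choose(n1+n2, n1) ≤ 2e5`, otherwise a tie-corrected normal approximation;
  the output records which route was taken.
* `route_test` screens both groups with Shapiro–Wilk at α = 0.05 and routes
  to the t test only if neither rejects; groups with n < 3 force the
  nonparametric route and are flagged.
* `partial_corr` residualises x and y on the covariates by OLS and
  correlates the residuals; the Spearman variant midrank-transforms x, y
  **and the covariates** first (the common SPSS behaviour). Significance
  uses t = r√(df/(1−r²)) with df = n − 2 − k. One-tailed tests take the
  positive direction, the implied direction for all burden–WMH hypotheses
  here. Correlations use pairwise-complete observations.
* `stepwise_forward` uses SPSS-convention entry/removal thresholds 0.05/0.10
  (the published analysis names the software but not the criteria), adds the
  smallest-entry-p candidate, removes any included predictor whose p rises
  above the removal threshold, and reports standardized βs, model R² and F,
  plus would-be βs and ps for the excluded candidates. Candidate sets with
  condition number above 1e8 are refused, naming the offending pair.

Calibration properties verified by the test suite: the one-tailed partial-
correlation p-value is uniform under a common-cause null (rejection
0.05 ± 0.01 at α = 0.05 over 10 000 cohorts of n = 36); the estimate matches
the closed-form partial correlation of a specified trivariate Gaussian
within ±0.03 at n = 5000; and with a single true predictor (β = 0.8,
n = 200, noise SD 0.5) stepwise recovers it first in ≥ 95 % of 500 runs.
Note that with three pure-noise co-candidates tested at entry p = 0.05, a
noise variable also enters in roughly 14 % of runs — that is the designed
per-candidate false-entry rate of the procedure, not a defect.

## The synthetic cohort

`make_cohort` draws one five-variate latent Gaussian per case over
(age, HPτ, Aβ, SI, WMH) with a configurable correlation matrix (checked
symmetric, unit-diagonal, PSD), adds a mean shift for the AD group (defaults
lift tau, amyloid and the WMH latent, leaving age and SI alone — the pattern
the reference study reports), and maps latents to observed scales by strictly
monotone transforms: age = 84.4 + 7.7·z years; pathology burdens
exp(μ + 0.8·z) percent (lognormal-like, capped at 100); SI = 0.2 + 0.4·Φ(z),
inside the plausible 0.2–0.6 range; and the WMH latent through three fixed
cutpoints (−0.8, 0.4, 1.4) to the ordinal 0–3 score — a probit-style
discretisation chosen as the simplest monotone rule, a modelling choice and
not a claim about how raters behave. Regional values reuse the case latent
with small independent regional noise (SD 0.3, variance renormalised);
totals apply the package's own aggregation rules. The default composition is
36 cases with 23 AD, mirroring the reference cohort. The latent draws are
attached as an attribute so calibration tests can check the copula directly.

## The end-to-end pipeline

`run_pipeline` chains generate → quantify → measure → score → analyze with a
single root seed from which every montage, vessel and mask derives a
deterministic sub-seed: identical config + seed give byte-identical CSVs.
Per case it paints and quantifies 24 AT8 and 24 4G8 montages (location
burdens = regional truth × {1.5, 1.0, 1.0, 0.5} for sulcus/midsection/gyral
tip, averaging to the regional truth), renders and measures 40 vessels, and
generates and rates 4 lesion masks whose diameters realise the case's true
scores. Stage failures abort with the stage name attached.

Problem sizes: the full-study profile used by the validation scripts runs 36
cases at 96-px tiles with 435.2/96 ≈ 4.53 μm/px — the same 1.7 mm² field as
the 512-px/0.85 μm default, sampled more coarsely — because at full
resolution a 36-case × 48-montage run is a multi-hour batch job, while the
coarse profile finishes in about a minute and preserves every structural
property the tests assert (the duality is exact at any scale). Unit tests go
smaller still (48–64 px tiles). These sizes are the package's chosen
trade-off between fidelity and turnaround.

## Known limitations

* The RGB boxes and the 100 μm² filter are taken as given calibration
  constants; nothing here re-derives them from stained material.
* One vessel per field is assumed (mirroring manual vessel selection); there
  is no vessel detection in whole-slide images, and SVD is measured as wall
  thickening only — perivascular spaces, blood–brain-barrier damage and
  amyloid angiopathy are out of scope.
* Lesion masks stand in for rated T2 hyperintensities; no MR physics, noise
  or registration is simulated, and no basal-ganglia subscales are rated.
* The ordinal ARWMC generation and the latent-Gaussian cohort are modelling
  conveniences; real rater behaviour and real joint distributions of
  pathology are richer than a five-variate copula.
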