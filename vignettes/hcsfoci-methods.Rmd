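---
title: "Methods: high-content foci counting, micronucleus scoring and plate statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content foci counting, micronucleus scoring and plate statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsfoci)
```

## The assays being modelled

`hcsfoci` implements the image- and plate-analysis side of a high-throughput
genotoxicity screen built around DNA double-strand-break foci.  A DNA repair
protein such as 53BP1 accumulates at double-strand breaks as discrete bright
sub-nuclear spots ("foci", roughly one focus per break), which an automated
microscope images in two channels: a DNA counterstain (Hoechst) for nuclei
and an immunostain (e.g. Atto488) for the foci.  The readout is the mean
number of foci per selected nucleus, aggregated over 500 cells per well, 5
replicate wells and 3 independent experiments (7500 cells per condition).
Companion assays share the plate logistics: the cytokinesis-block
micronucleus (CBMN) assay scores the percentage of micronucleated cells among
binucleated cells (about 25 % of 1000 analysed cells per well under
cytochalasin-B block), WST-1 absorbance (A450 − A690) gives viability and the
Cmax concentration rule, and DHR123 fluorescence time courses report reactive
oxygen species as fold change over time-matched controls.

No public microscope data accompany this assay family, so the package ships a
synthetic field generator with complete planted ground truth; every pipeline
stage is validated as a parameter-recovery exercise against that truth.

## The synthetic field generator

`simulate_field()` renders elliptical nuclei (equivalent-circle radius
`nucleus_radius_mean` ± `nucleus_radius_sd`, eccentricity uniform below
`eccentricity_max`, random orientation) at `nuclear_level` counts over a
`background_level` floor, and plants per-nucleus Poisson(`foci_lambda`) focus
discs of radius `foci_radius` at `foci_peak` counts above background in the
immunostain channel.  Deliberate artifacts reproduce what the QC rules must
reject:

* **clumps** (`clump_fraction`): a second ellipse fused at 30–60 % radius
  overlap, emulating touching nuclei that segment as one oversized object;
* **border nuclei** (`edge_fraction`): planted crossing the field edge;
* **pan-nuclear staining** (`pan_nuclear_fraction`): the whole nucleus is
  rendered at `nuclear_level + foci_peak / 2` in the immunostain channel
  instead of discrete foci — the classic γ-H2AX-style artifact that must not
  be focus-counted.

Noise is applied last: optional Poisson shot noise on the expected counts,
then additive Gaussian read noise (`noise_sd`), rounded and clipped to the
16-bit range.  All stochastic truth is drawn *before* rendering, so
`render = FALSE` returns the identical truth table at negligible cost, and
identical `(params, seed)` give bit-identical images.

Placement is rejection sampling with a cap of 100 attempts per cell; if the
cap is reached the achieved count is reported with a warning.  Planted focus
centres are kept one focus diameter plus 2 px apart and one focus radius
plus 2 px inside the nuclear boundary.  The extra 2 px are deliberate: with
separation exactly two focus radii the detector's merge rule cannot
distinguish adjacent foci, while much larger separations measurably truncate
high Poisson counts by exhausting placement room (about −7 % of the mean at
λ = 8 with 12 px separation in default nuclei; < 0.5 % at the default 8 px).

`simulate_mn_field()` renders CBMN fields: a cell is binucleated with
probability `binucleation_rate` (two nearly round nuclei at 0.8 × the single
radius, centroid gap at most 2.5 mean radii, never touching), carries
micronuclei with probability `mn_prob` (count distribution
`mn_count_given_positive`, radius `mn_radius_fraction` of the main radius,
planted a few pixels clear of the pair).  Cells are spaced so nuclei of
*different* cells stay beyond the pairing-gap criterion (centre spacing
7.5 × the mean radius); in the real assay the deliberately low plating
density plays this role.

Default geometry — 1024 × 1024 px fields, 120 cells, 30 px nuclei, 3 px
foci — was chosen once so that the downstream defaults work untuned.  The
simulator works in pixel units throughout because the assay defines no
physical pixel size.  It does not attempt optical realism: no point-spread
function, z-structure, chromatic shift or channel crosstalk.  Passing tests
therefore demonstrate correctness of the measurement logic under the assumed
statistical structure, not robustness to optics-specific effects.

## Nuclei segmentation and QC

`segment_nuclei()` smooths the DNA channel (Gaussian, `smooth_sigma` = 2 px),
thresholds globally (Otsu by default; a fixed operator threshold mirrors HCS
instrument practice), fills holes and labels connected components
(8-connectivity by default; the 4-connected variant is available).  Geometry
is measured on the binary mask: area as pixel count, centroid, perimeter by
Moore-neighbour contour tracing (axial steps 1, diagonal steps √2, scaled by
0.95 to correct the staircase overshoot of digitised smooth contours — a
digital disc then measures 2πr within half a percent).  Two-direction
Crofton-style estimators were rejected because axis-aligned shapes overshoot
circularity far past 1 and fused clumps read as near-circular.

QC assigns exactly one status per component with precedence border > size >
circularity:

* `excluded_border`: any pixel on the first/last row or column;
* `excluded_size`: area outside `[0.3, 2.2] × π r̄²` (fragments and fused
  clumps — clumps are excluded rather than watershed-split, matching the
  assay's own practice of rejecting nuclei too close together);
* `excluded_circularity`: `4πA/P²` (clamped at 1) below 0.8 — a 2:1 ellipse
  scores ≈ 0.84, a fused pair at 40–60 % overlap ≈ 0.71–0.80.

A uniform (blank) image returns zero records rather than an error.

## Focus detection

Within each selected nucleus, `detect_foci()`:

1. applies a white top-hat (structuring disc radius `2 × foci_radius + 1`) to
   the immunostain channel, removing everything wider than a focus;
2. finds local maxima of the response and keeps those exceeding
   `median + k_mad × MAD` of the top-hat signal *inside that same nucleus*
   (`k_mad` = 5, MAD with the usual 1.4826 consistency constant).  A
   per-nucleus robust threshold makes the defaults portable across intensity
   regimes, where a single global threshold would need operator re-tuning;
3. merges maxima closer than `min_separation` (= one focus diameter),
   keeping the brighter;
4. requires the connected supra-threshold spot beneath each peak to have
   area within `[2, 80]` px².

One numerical subtlety matters: peaks are *located* on a lightly smoothed
copy of the response (`response_sigma` = 1 px) while all amplitudes,
thresholds and spot geometry stay on the raw response.  Without this, camera
noise on the flat top of a focus disc creates twin peaks that survive
merging, and shifts the apparent peaks of two adjacent foci inside the merge
distance; both effects were measured at the percent level and vanish with
peak-only smoothing (exact per-nucleus recovery at λ ∈ {0, 1.3, 8} in the
package's own tests).  Smoothing the response used for thresholding instead
would be wrong: it spreads and merges the supra-threshold spots and breaks
the spot-area rule.

`flag_pan_nuclear()` guards the counts: a nucleus whose 10th-percentile
immunostain signal exceeds 3 × the median background outside nuclei is
flagged and keeps `foci_count = NA`, dropping out of per-well means.

## Micronucleus scoring

`pair_binucleates()` pairs QC-selected nuclei greedily by increasing
centroid gap (ties by label), accepting gaps up to `max_pair_gap` = 2.5 mean
equivalent diameters and area ratios within `[0.5, 2]`; each nucleus joins at
most one pair and the result is deterministic.  Fused binucleates never reach
pairing: they segment as one oversized component and are rejected, as the
instrument rejects overlapping binucleates.  `detect_micronuclei()` then
counts DNA-positive components with area in `[1/256, 1/9]` of the pair's
mean main-nucleus area (diameter 1/16–1/3 of the main nucleus — the standard
CBMN size convention) whose centroid lies within `mn_max_distance` = 20 px of
the nearer main-nucleus boundary.  `mn_frequency()` reports
`100 × micronucleated / binucleated`, erroring on zero binucleates.

## Plate statistics

`well_mean_foci()` averages the focus counts of the first `cap` = 500
selected, unflagged nuclei in (field, label) order — a deterministic
counterpart of the instrument's fixed per-well cell budget; seed-controlled
random subsampling is available.  `condition_summary()` is the mean ± sample
SD of the 15 well statistics.  Hypothesis testing follows the assay's
convention exactly: omnibus Kruskal–Wallis across conditions, then each
condition vs control by two-sided Mann–Whitney at α = 0.05, with no
multiplicity correction by default (a Holm option exists).  The Mann–Whitney
p-value is exact by enumeration for tie-free samples up to n = 10 per group,
otherwise normal approximation with tie and continuity corrections; the
all-tied degenerate cases return p = 1 (H = 0 for Kruskal–Wallis).  The
rank tests are computed via R's `stats` machinery behind this interface; the
package's tests check the exact path against an independent brute-force
enumeration of all group assignments.

## Plate-reader analytics

`wst1_viability()` computes `(A450 − A690)` minus the mean blank, as percent
of the mean control signal, floored at 0.  `find_cmax()` operationalises
"highest concentration that does not affect viability" as mean ≥ 85 % of
control *and* Mann–Whitney vs control non-significant at α = 0.05 — the
85 % floor reflects the assay's tolerance of ≤ 15 % viability loss at its
standard top concentration.  When both compared groups are internally
constant (a noiseless plate), the rank test carries no information and only
the mean rule applies.  `series_from_cmax()` returns the tested series
{Cmax, Cmax/2, Cmax/5}.  `dhr123_fold_change()` divides each well's
fluorescence by the mean time-matched control and applies the same test
battery per timepoint.  `repair_halftime()` linearly interpolates a focus
time course to the first time the excess over baseline halves from its peak,
reporting censoring when the window never gets there.

## Problem sizes and determinism

The recovery studies in the tests and in `scripts/acceptance.R` use the
assay's own design points: foci conditions at 15 wells × 500 nuclei (7500
nuclei, default 1024² geometry, ~5 fields per well) with planted means 1.3
(unexposed control), 3.1 (24 h residual) and 8 (30 min post-irradiation)
foci per nucleus; the micronucleus condition at 15 wells × 1000 cells with
25 % binucleation, scored on 15 px-radius nuclei (40 cells per field) so a
full condition stays at desk scale.  Every stochastic step derives from a
single user seed via a seed table, so runs are exactly reproducible.

## Known limitations

* The generator's artifacts are stylised; real clumps, debris and uneven
  illumination are richer than the fused-pair, border and pan-nuclear models.
* Circularity near the 0.8 threshold is estimator-dependent: the planted
  truth classifies a fused pair from the pre-noise mask, the pipeline from
  the post-smoothing mask, and the two can disagree for borderline overlaps
  (accuracy invariants are therefore stated on clump-free fields).
* Micronuclei touching a main nucleus merge with it at segmentation and are
  not recoverable; the generator plants them with a small clearance, which
  matches scoring conventions but not every real morphology.
* The nonparametric battery inherits the assay's design: with n = 15 wells
  per condition the Mann–Whitney test is approximate (normal with
  corrections), and no multiplicity correction is applied by default.
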