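---
title: "Semiquantitative DAB scoring: models, parameters and design choices"
author: "DABquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantitative DAB scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(DABquant)
```

## The measurement problem

Immunohistochemistry with a DAB (3,3'-diaminobenzidine) chromogen
deposits a brown precipitate wherever the targeted antigen is bound,
over a blue hematoxylin counterstain that marks every nucleus.
Semiquantitative scoring asks, per stained section: *what fraction of
cells are positive, and how many positive cells are there per mm²,* in
the most affected region of the tissue?  DABquant implements that
question as a reproducible pipeline and pairs it with a synthetic image
generator whose ground truth is known exactly, so each stage can be
validated quantitatively rather than by eye.

The pipeline has five stages, each an exported function:

1. **Optical density** — `rgbToOD()`.  Under the Beer–Lambert law the
   transmitted intensity of an absorbing stain is `I = I0 * 10^(-OD)`,
   so `OD = -log10((v + 1) / 255)` per channel (the `+1` guards 8-bit
   zeros; it is dropped, via `guard = 0`, for continuous synthetic
   renders).  OD is linear in chromogen concentration, which is what
   makes the next step a matrix inversion.
2. **Color deconvolution** — `deconvolve()`.  Per pixel,
   `OD = M %*% c` where the columns of `M` are unit-norm stain OD
   vectors and `c` the stain concentrations; the package inverts `M`
   and clamps small negative concentrations to zero, reporting the
   clamped fraction.  The default `M` uses the community-standard H-DAB
   reference vectors (hematoxylin ≈ (0.650, 0.704, 0.286), DAB ≈
   (0.269, 0.568, 0.778)) with the residual completed as their
   normalized cross product; all nine numbers are overridable in the
   YAML configuration because published protocols rarely print the
   vectors actually used.
3. **Cell detection** — `detectCells()`.  Nuclei are segmented from the
   hematoxylin + DAB sum (so a strongly DAB-stained cell that masks its
   counterstain still counts as a cell), and each cell's mean DAB OD is
   measured on the *unsmoothed* DAB map.
4. **Positivity** — `classifyPositive()`.  A cell is positive when its
   mean DAB OD strictly exceeds the threshold τ.  The threshold is
   openly arbitrary in this kind of protocol; it is therefore a single
   declared parameter (default 0.2 OD), and every validation property
   in the test suite is exercised under the defaults.
5. **ROI scoring and statistics** — `findPeakROIs()`,
   `buildComparisonTable()`.  Square windows of fixed area (default
   0.1 mm², side ≈ 316 µm) are placed to maximize the positive-cell
   count; per-window metrics are `pos_percent` and `pos_per_mm2`; group
   comparisons use a two-tailed Mann–Whitney U test at the 5% level.

## Peak and subpeak windows

Because the diseases being compared are spatially "patchy", scoring the
*most affected* region is more informative than a whole-section
average.  The original protocol placed the window by eye; DABquant
replaces that with a defined maximization:

* the score of a window is its count of positive cells whose centroid
  falls in the half-open square `[x, x+side) × [y, y+side)` — at fixed
  area this is equivalent to positives per mm², and it does not favor
  nearly-empty windows the way percent-positive would;
* the search runs over a grid of origins with stride `side/10`
  (≈ 31.6 µm at the default area), plus flush windows at the far edges;
  ties are broken by higher percent positive, then the smallest (y, x);
* the **subpeak** is the best window with *zero* area overlap with the
  peak, so the two readings never double-count one hotspot;
* when both windows are requested, the peak is the best window that
  still admits a disjoint partner.  On fields at least three window
  sides long this constraint is vacuous; on smaller fields an
  unconstrained mid-field argmax can make a zero-overlap subpeak
  geometrically impossible, and the jointly best disjoint pair is the
  faithful reading of "two separate ROIs".

The grid search at 1-px stride is *exactly* equal to exhaustive
enumeration (asserted against an independent brute-force oracle in the
tests).  At the default stride the captured peak score averages ≥ 95%
of the exhaustive optimum on clustered fixtures, with per-fixture
worst cases around 0.9 — peak counts are small integers, so a 5 µm
window offset can cost a couple of cells; reduce `stride` if exact
optima matter more than runtime.

Per subject, the three analysis modes mirror the reporting structure of
cohort studies that motivated the package: both windows pooled (2
values per subject), peak only, and the per-subject mean of the two
(`collectValues()`).  An empty window yields a missing percent-positive
value; missingness propagates into the mean-of-two and dropped values
are counted in the run log.

## Statistics

`summarizeGroup()` reports mean, median, 25th/75th percentiles (linear
interpolation between order statistics, R's type 7), their difference
as the IQR, and the n−1 sample SD.  Published tables of this kind are
occasionally internally inconsistent by a point or two in the IQR
(rounding order is unknowable), so the method is *declared* rather than
reverse-engineered; the test suite checks the identity IQR = P75 − P25
against printed rows that are internally consistent.

`mannWhitneyU()` is authored in the package: midranks for ties; exact
two-tailed p by full enumeration of rank assignments when the combined
sample is ≤ 16 without ties; otherwise the normal approximation with
tie correction and continuity correction.  `stats::wilcox.test` serves
only as an independent oracle in the tests — both paths agree to
machine precision on sweeps of small samples and tied cohorts.  Under a
null with the study's group sizes (15 vs 21, values rounded to one
decimal to force ties) the empirical rejection rate at the nominal 5%
level is 4.4–4.9% over 10,000 replicates: the continuity correction
makes the test slightly conservative, which is the test's true
behavior, not an implementation artifact.  No multiple-testing
correction is applied; raw two-tailed p-values are reported, as is
conventional for this table layout.

## The synthetic cohort generator

`simulateCohort()` emulates the study design the analysis assumes:
three groups (healthy volunteers n = 15, GERD n = 21, EoE n = 20), one
stained section per subject, randomized and blinded before analysis.

**Subject-level parameters.**  Each subject draws a positive fraction
`f` from a Beta distribution matched by moments to the group mean/SD
(bounded support and two free moments make Beta the natural choice; the
defaults 0.38 ± 0.31, 0.59 ± 0.28, 0.63 ± 0.29 follow the
percent-positive summary of the emulated study's iNOS tables), and a
total cell density `d` from a moment-matched Gamma (positive support).
A zero SD degenerates to a constant, so edge cases like `f = 0` are
exactly representable.

**Spatial structure.**  Negative cells form a homogeneous Poisson
process of intensity `d(1−f)`; positive cells a Thomas cluster process
of total intensity `d·f` (Poisson parents, Gaussian dispersal, parents
sampled in a 3σ buffer so the process is stationary across the field).
Nuclei closer than 0.8× the sum of their radii are rejected and
resampled with bounded retries; exhausting the retries raises an error
naming the density parameter, because it means the requested density
exceeds what the hard-core rule can pack.

The patchiness defaults are 10 parents/mm² with σ = 100 µm.  This was
fixed by a design-time feasibility study: much sparser parent
intensities concentrate *all* positives into one or two clusters whose
core density exceeds both the hard-core packing limit and any
segmentation's resolving power, while much denser/wider settings wash
the hotspots out entirely.  The default produces roughly ten visible
hotspots per default 1.05 mm² field — patchy at the scale of the
316 µm ROI side, so peak-window scoring is genuinely exercised — with
core positive-density enhancement around 1.6×.

**Density scale.**  The default total density is 2500 ± 800 cells/mm²
for all groups, with group differences carried by the positive
fraction.  This is the deliberate resolution compromise: the absolute
positives/mm² levels printed in the emulated study's tables
(≈ 2800–4700 in peak windows) imply in-window total densities around
7500/mm², at which 2.75 µm nuclei at 0.5 µm/px merge into connected
carpets that no threshold + watershed segmentation can resolve to the
≥ 95% recovery this package demands of itself.  Consequently the
generator reproduces the *fraction* structure of the tables
quantitatively and the *density* structure only qualitatively (ordering
and spread, not absolute scale).  Percent-positive readings are
scale-free and unaffected.

**Rendering.**  Each nucleus is a filled disc of stain concentrations
(hematoxylin for all, DAB at 0.6 OD for positives and 0.05 for
negatives); overlapping discs add their optical densities (absorbers
stack).  Per pixel, `RGB = 255 · 10^(−M c)` — base 10, matching the OD
definition so that rendering and deconvolution are exact inverses;
Gaussian noise (SD 0.02) is added in OD space and the result clipped to
[0, 255].  The in-memory render is continuous; the noiseless
render/deconvolve round trip recovers concentrations to < 1e-6, while
8-bit quantization (applied only when writing TIFFs) limits file-based
round trips to ~1e-3, which is why the exactness oracle runs on the
continuous array.

**What the generator does not emulate.**  Epithelial layering, dilated
intercellular spaces, multiple tissue fragments, scanner artifacts, and
cytoplasmic (as opposed to nuclear-disc) staining are all absent.
Passing tests therefore demonstrate that the *computational* pipeline
is correct and calibrated on images satisfying its geometric
assumptions — not that it would segment real esophageal biopsies at
these accuracies.

## Detection parameters and their rationale

| parameter | default | meaning |
|---|---|---|
| `sigma` | 1.0 µm | Gaussian smoothing of the H+DAB sum before thresholding |
| `nuclearThreshold` | 0.2 OD | foreground threshold on the smoothed sum |
| `minArea` | 16 µm² | objects below this are discarded |
| `maxArea` | 40 µm² | objects above this are watershed-split |
| `dabThreshold` (τ) | 0.2 OD | strict positivity threshold on mean DAB OD |
| `seedSeparation` | 2.75 µm | minimum seed spacing for splitting (≈ one nucleus radius) |

These defaults were fixed together by a segmentation study on
default-condition synthetic fields before the validation thresholds
were frozen.  Two couplings matter.  First, threshold vs. smoothing: a
low threshold on a smoothed map dilates each mask — at 0.1 OD the
dilation is ~2–3× and realistic fields percolate into a single
connected carpet; 0.2 OD with 1.0 µm smoothing keeps masks near the
true disc outline while faint (hematoxylin-only) nuclei still clear the
16 µm² minimum.  Second, `maxArea` vs. nucleus size: splitting is only
attempted above `maxArea`, so it must sit between one nucleus
(~24 µm²) and two (~48 µm²); the conventional much-larger setting never
routes touching pairs to the splitter at all.

Splitting itself is marker-controlled: peaks of the distance transform
(local maxima within a `0.8 × seedSeparation` radius, interior ≥ 1 µm)
seed a spatially dominated region growing (`EBImage::propagate` with
large `lambda`), so pieces meet at the equidistance line between seeds.
EBImage's tolerance-merging watershed was measurably worse on triples;
the seeded form also matches the natural reading of "distance-transform
peaks as seeds".  Centroids are intensity-weighted for unsplit objects
(exact for an isolated disc) and reported at the seed plateau for split
pieces, which is what keeps merged-pair centroid errors inside a 2 µm
matching tolerance.  Border-touching cells are retained: window
membership is a centroid decision made later, and discarding them here
would bias window counts.

Under the defaults the detector recovers ≈ 95–97% of ground-truth
nuclei within 2 µm with ≥ 99% positivity-label agreement (measured
in `test-acceptance.R` on 640 × 640 px default-condition fields), and
the count-pooled group positive fraction lands within 0.01–0.03 of the
configured Beta means.

## Estimating the group positive fraction

Three estimators of a group's positive fraction behave very
differently under clustering, and the package's validation uses the
only consistent one:

* the **pooled-count estimator** Σ positives / Σ cells over a group's
  images is consistent for the configured Beta mean (density and
  fraction are drawn independently);
* the **mean of per-subject ratios** is biased *downward* by
  cluster-count variance — a subject can legitimately draw zero
  parents, contributing a zero ratio;
* the **peak/subpeak window readings** are biased *upward* by
  construction: an argmax over windows of a clustered process
  oversamples hotspots.  This enrichment (≈ +0.10 at the default
  patchiness) is not an artifact — "most affected region" scoring is
  *designed* to be enriched — but it means window readings estimate
  peak burden, not the subject-wide fraction.

## Blinding, determinism, problem sizes

All randomness flows from one master seed: per-subject sampling seeds,
per-subject noise seeds and the blinding permutation are derived from
it by a single `sample.int` draw, so a cohort is reproducible bit for
bit.  The blinded manifest is a seeded row permutation with the group
column removed; the key inverts it exactly, and blinded versus
unblinded analyses agree per subject by construction (labels enter only
at the statistics stage).

The validation suite runs on reduced problem sizes chosen as the
package's own test geometry: 640 × 640 px fields (0.1 mm²) for
parameter recovery (150 images over 10 seeds), 420 × 420 px fields for
pipeline smoke tests, and 10,000 replicates for the test-level
simulation.  The statistical conclusions are size-free; the default
2048 × 2048 px field is exercised by the same code paths.

## Known limitations

* The stain vectors of any given scanner/protocol differ from the
  defaults; on real data they should be calibrated and supplied in the
  configuration.
* The generator's density scale is a resolution compromise (see above);
  absolute positives/mm² from default synthetic cohorts sit below the
  levels of the clinical tables that motivated the group structure.
* White-point estimation is not performed (`i0 = 255`); synthetic
  backgrounds are white, and real slides with tinted backgrounds would
  need per-image calibration before the OD transform.
* Cells are equated with nuclei; no cytoplasmic expansion is modeled,
  so membrane/cytoplasmic stains would be under-measured.
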