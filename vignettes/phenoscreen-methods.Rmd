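---
title: "Methods: high-content analysis of phenotype-switching screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content analysis of phenotype-switching screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Melanoma cells move along a reversible phenotypic axis between an
invasive, poorly differentiated state and a proliferative, differentiated
(pigmented, MITF-high) state. A plate-based high-content screen for
microenvironmental agonists of this switch reads out two phenotypes per
well after several days of treatment:

* **proliferation** — the number of cells per well, counted from nuclear
  staining;
* **differentiation** — cell elongation, the ratio of the minor to the
  major axis of each cell mask, whose change accompanies the
  differentiated morphology.

An agent that raises both readouts relative to same-plate vehicle controls
is a *dual-phenotype* hit — the biology of interest, since metastatic
outgrowth favours cells that are simultaneously proliferative and
differentiated. `phenoscreen` implements the complete computation: image
simulation, segmentation, per-cell morphometry and classification,
control-referenced scoring, and hit calling, plus three small companion
image/absorbance quantifications.

# The composite Z-score

Each treated replicate well receives a signed Z-score against the vehicle
wells of its stratum (same plate, same serum level, same vehicle):

$$Z_i = \frac{x_i - \hat\mu}{\hat\sigma},$$

where $\hat\mu$ and $\hat\sigma$ are the mean and sample standard
deviation ($n-1$ denominator; the estimator is a package choice) of the
measurement in those control wells. The $n$ replicate Z-scores form a
vector $\mathbf{z} \in \mathbb{R}^n$, and the composite statistic is its
signed scalar projection onto the unit diagonal
$\mathbf{v} = (1/\sqrt{n}, \dots, 1/\sqrt{n})$ — the direction of perfect
reproducibility:

$$\hat Z = \mathbf{z} \cdot \mathbf{v} = \frac{1}{\sqrt n}\sum_{i=1}^n Z_i.$$

Two exact properties anchor the implementation and its tests: if all
replicates share the same score $z$ then $\hat Z = \sqrt n\, z$, and under
an i.i.d. standard-normal null $\hat Z$ is again standard normal for any
$n$, so $|\hat Z| > 1.96$ has a raw false-positive rate of 5% per
condition (`null_calibration()`). No multiple-testing correction is
applied anywhere — the composite is a reproducibility-weighted effect
size, not a corrected p-value — and the package documents the raw rate
instead.

The projection is *signed*: increased and decreased proliferation are
distinguished in every downstream table and heatmap. An unsigned
projection length is available via `composite_z(z, absolute = TRUE)`.
Degenerate control strata ($\hat\sigma = 0$) are refused with an error
rather than regularized; inflating a zero variance would fabricate
significance.

# Synthetic plates and images

No screen images are distributed with the package; the synthetic-data
module generates everything the pipeline consumes, with exact per-cell
ground truth, so each stage is testable against known answers.

**Plate design.** `generate_plate()` lays out agents × dose series ×
serum levels × replicates plus vehicle wells on 96-well plates, never
splitting a stratum's treated wells away from its controls. Dose series
are geometric, anchored at the top dose: the screen's printed ranges
(e.g. EDN3 1.56–100 nM, SCF 3.125–200 nM, Dopamine 4.68–300 µM) are all
7-point 2-fold dilutions from the maximum, and `screen_agents()` ships
them as defaults.

**Control wells per stratum: 24 by default.** Every dose-level composite
on a plate shares the same $\hat\mu, \hat\sigma$; with few controls the
noisy shared $\hat\sigma$ correlates all composites, which inflates the
probability that a null agent passes the cutoff at two or more doses in
both measurements at once. A control-count calibration with
`screen_null_rate()` (1000 simulated null screens, 7 doses × 4
replicates, cutoff 1.96, min_doses 2) gives a dual-phenotype false-call
rate of roughly 6% at 6 controls, ~1% at 16, and <0.5% at 24. The
default plate design therefore dedicates three columns (24 wells) per
stratum to vehicle, which keeps the false dual-call rate comfortably
below 1%.

**Effect models.** Agents act through a Hill dose–response
(`effect_model()`): occupancy $d^h/(d^h + \mathrm{EC}_{50}^h)$ scales the
expected cell count by $1 + E_{max}^{count}\cdot occ$ and shifts mean
elongation additively by $E_{max}^{elong}\cdot occ$ (clipped to $(0,1]$
with a warning). Vehicle wells are untouched by construction. Realized
well counts get a log-free Gaussian perturbation with CV 0.1 — a typical
well-to-well seeding variability for passaged lines.

**Rendering.** Cells are filled ellipses (the elongation readout is an
axis ratio, which ellipses parametrize exactly; dendritic in-vivo
morphology is out of scope). Per cell: semi-major axis uniform on 12–20
px (a 10× objective scale), elongation Beta-distributed around the well
mean (concentration 25), a circular nucleus of half the semi-minor axis
clamped to 4–8 px. The four channels are:

* `nuclear_short` — background 100 counts, +400 over the body, +2000
  over the nucleus, Gaussian read noise σ = 200 (nuclear SNR ≈ 10);
* `nuclear_long` — the *same clean scene* multiplied by the exposure
  gain (default 3×) before fresh noise, mirroring a 0.1 s vs 0.3 s
  exposure pair: nuclei dominate the short image, bodies become
  thresholdable in the long one;
* `green` / `red` — per-cell nuclear reporter intensities drawn from
  positive/negative mixtures (green 800 ± 80 vs 200 ± 50; red 600 ± 60
  vs 150 ± 40) that straddle the classification thresholds.

Intensities are 16-bit counts. The classification thresholds (500, 360,
283) are published as raw intensities without a stated camera bit depth
or background, so the generator's defaults are chosen to make them
meaningful rather than claimed faithful to the original instrument.
Placement is non-overlapping by default (bounded rejection sampling on
bounding circles; an error after 500 retries per cell flags infeasible
densities), with `allow_overlap = TRUE` for segmentation stress tests.
Optional Poisson shot noise can be toggled; read noise dominates at
these levels, so the default is Gaussian-only.

What the generator deliberately does **not** emulate: optical PSF blur,
uneven illumination and vignetting, focus drift, debris and apoptotic
fragments, overlapping/confluent monolayers, and dendritic shapes.
Passing tests therefore demonstrate correctness of the *computation*
(segmentation logic, feature definitions, statistics), not robustness to
every artefact of real microscopy.

# Segmentation

Stage one (`segment_nuclei`) detects nuclei on the short exposure: white
top-hat transform with a disc structuring element (radius 15 px,
~1.5× the expected nucleus radius — the vendor parameters are
unpublished, so this default is declared, not claimed faithful), then an
automatic isodata threshold of the top-hat image, connected components,
a 30 px minimum-area filter, and an optional distance-transform
watershed that splits touching pairs (on by default). Two numerical
choices matter:

* the isodata iteration is initialized at the intensity *midrange*
  rather than the mean, which keeps it out of the dominant background
  mode when bright objects are rare (a sparse field would otherwise be
  thresholded inside the noise);
* the automatic threshold is floored at median + 5 MAD of the top-hat
  image, so a signal-free field returns zero objects instead of noise
  specks.

Stage two (`segment_cell_bodies`) applies a single global threshold to
the long exposure and partitions the foreground among the nucleus seeds
by seeded region growing (EBImage's `propagate`). The automatic
threshold is computed over non-nucleus pixels: the nuclei are already
known foreground, and excluding their much brighter mode leaves a
bimodal background/body histogram for the intermeans rule; the resulting
single value is applied to the whole image. Foreground components
containing no seed are discarded; nucleus pixels are always unioned into
their body, so a seed that falls outside the thresholded foreground
degrades to its nucleus mask with a warning, and every body contains
exactly its own seed. A region with two seeds is always split, never
merged — one nucleus per cell is what makes the count a proliferation
readout. Border-touching objects are flagged, not removed; exclusion is
a feature-stage policy.

# Features and classification

**Elongation** follows the literal chord definition: the major axis is
the longest straight segment between boundary-pixel centres that lies
entirely within the mask; the minor axis is the longest in-mask chord
perpendicular to it. Exact perpendicularity is measure-zero on a pixel
grid, so a ±2° tolerance is applied. Chord length is the Euclidean
distance between pixel centres; a single-pixel mask is 1.0 by
convention, and a direction in which the mask is one pixel wide
contributes length 1. The implementation sorts candidate boundary pairs
by length and returns the first fully-interior one; the test suite holds
it to within 1 px per axis of an exhaustive all-pairs oracle. A faster
moment-based variant (equivalent-ellipse axes) is available as
`method = "moment"` but the exact chord method is the default, since
whether the original instrument software used chords or moments is
unknown. Elongation is computed on the **cell-body** mask; reporter
intensities are averaged over the **nucleus** mask only.

**Classification** uses strict inequalities at the printed thresholds:
fish profile GFP > 500 and tdTomato > 360; human profile RFP > 283. A
cell at exactly the threshold is negative.

**Well summaries** count all cells (border-touchers included — a clipped
cell is still a cell) but exclude border-touching cells from shape
means, whose clipped masks bias elongation. Means are reported for all
cells and per reporter class; an empty class yields NaN rather than a
silent 0.

# Scoring and hit calling

`score_screen()` scores two measurements by default: total cell count
(proliferation) and mean elongation of the green-reporter-positive
population (differentiation); the mapping is a named-vector argument, so
all-cell or red-class variants are one keystroke away.
`build_matrix()` arranges composites as the screen's heatmap — rows
(agent, dose) ascending, columns (serum, measurement) — with missing
conditions as explicit NA, never 0.

`call_hits()` uses cutoff $|\hat Z| \ge 1.96$ at $\ge 2$ doses per
measurement, evaluated separately per serum condition; a dual-phenotype
call requires proliferation-up and differentiation in the *same* serum
condition. The original screen never states its significance rule — this
default is the package's own operationalization and is recorded in every
report manifest. The 1.96/2-dose choice is deliberately permissive per
condition (raw 5% per composite) but specific at the agent level, as the
`screen_null_rate()` calibration above shows.

**Sign convention for differentiation.** The elongation measurement is
the minor/major ratio, which *falls* as cells become needle-like; yet
the synthetic effect models express differentiation as a positive
additive shift of that ratio's well mean, and the corresponding
composite rises. The package's default differentiation signature is
therefore `elong_direction = "increase"`, with `"decrease"` and
`"either"` as switches — the direction is a convention of the effect
encoding, not a biological claim, and reports record which was used.

# Companion quantifications

* `pigment_area_fraction()` — fraction of ROI pixels at or below a
  threshold on a brightfield image (black-vs-white thresholding of a
  larval tail). The threshold is user-supplied by default because the
  original value is unstated; fractions are comparable only within a
  fixed-threshold batch.
* `tumour_area()` — isodata (iterative intermeans) automatic threshold —
  the documented "default" auto-threshold of common image software —
  applied uniformly across a batch, then connected components with area
  and perimeter per object. Perimeters are boundary-pixel counts, which
  run a few percent below geometric circumference on smooth shapes.
* `melanin_relative()` — ordinary least-squares standard curve through
  (melanin concentration, A405) calibration points, inverted to map
  sample and vehicle absorbances to concentrations; the result is the
  ratio of means, 1.0 meaning vehicle-level melanin. No weighting is
  applied (the protocol gives no replicate structure to weight by). The
  ratio is invariant to the curve's concentration units.

# Problem sizes and determinism

Every stochastic function takes an integer seed and is exactly
reproducible for fixed (arguments, seed). The test suite and the
acceptance script use: 1000×1000 px fields with 50–200 cells for
segmentation recovery (20 fields); 600×600 px fields, 60-cell baseline,
one field per well for the 80-well end-to-end screen; 1000 simulated
screens for null specificity (summary-level simulation — the specificity
statistic depends only on well summaries, so rendering is bypassed
there); 100,000 draws for null calibration; masks up to 60×60 px for the
chord-oracle comparison. These sizes were chosen so the whole validation
runs comfortably on a laptop while leaving every statistical check
well-powered.

# Known limitations

* The vendor segmentation parameters (top-hat element size, threshold
  rules) are unpublished; defaults are sensible, documented, and
  configurable, but not claimed to reproduce the original software.
* Raw intensity thresholds are instrument-specific; applying the
  printed values to other data requires matching the acquisition scale.
* The generator's ellipse cells cannot probe errors specific to
  irregular or dendritic morphologies, nor to dense confluence.
* Survival analysis, RNA-seq, pathway inference and histology scoring
  around the original screen are out of scope by design.
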