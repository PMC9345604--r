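---
title: "Quantifying the supraspinal connectome: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the supraspinal connectome: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supracount)
```

## The problem

Retrograde viral tracing from the spinal cord labels the nuclei of every
brain neuron whose axon reaches the injection site. After tissue clearing,
light-sheet imaging and registration to a reference atlas, each detected
nucleus is a point in atlas space with an intensity. supracount implements
everything downstream of registration: assigning points to brain regions
and hemispheres, collapsing counts through the region hierarchy, comparing
injection levels within animals, matching the two fluorophore channels to
identify dual-projecting neurons, quantifying injury-induced loss of label
("sparing"), and asking which regions' sparing separates animals that
recover locomotion from those that do not.

Image-to-atlas registration, the deep-learning cell classifier that
produces the point clouds, and behavioral scoring itself are out of scope:
the package consumes their outputs (point CSV/XML files, an annotation
volume, a metadata table with final locomotor scores).

## Region assignment and count collapse

Coordinates are micrometres in atlas space with the origin at the array
corner. A point at coordinate $c$ along an axis with voxel size $v$ belongs
to voxel $\lfloor c/v \rfloor$, which owns the half-open interval
$[vi, v(i+1))$. Points in label-0 voxels are counted as unassigned rather
than dropped, and out-of-bounds points are tallied separately, so every
stage's totals reconcile. Hemispheres split on a declared midline plane;
points exactly on the plane go to the left hemisphere — an explicit,
testable tie-break for an event of measure zero in real data.

Counts are reported at three levels: leaf regions, reporting regions and a
small set of summary categories (for example, the spinal, medial and
lateral vestibular nuclei under a single vestibular label). The two
collapse maps are configuration, not code: the full membership of the
summary categories is a curation choice, so the package validates totality
(every counted leaf must reach a summary) instead of hard-coding a region
count, and ships an editable template for the Allen-atlas case. Collapse is
a count homomorphism — collapsing then summing equals summing then
collapsing — and the test suite verifies this against recounts of raw
assignments.

The deep cerebellar nuclei sit so dorsally that ventrally collected
light-sheet data under-detects them; sparing analyses therefore support a
region exclusion list, with `"DCN"` excluded by default.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream guarantee is verified.

* **Counts.** Per-animal, per-region nucleus counts are negative binomial
  with mean $\mu_r$ and size $k$ (`dispersion`), i.e. variance
  $\mu + \mu^2/k$. Published tables report only means, SEMs and ranges;
  the default $k = 40$ reproduces the printed inter-animal spread of
  brain-wide totals (a range of roughly ±30% around the mean across ten
  animals). $k = \infty$ gives Poisson counts, and the suite checks both
  the overdispersed and the limiting regime.
* **Placement.** Nuclei are uniform within their region's voxels; no
  within-region density information is published, and uniformity is the
  assumption that makes the assignment oracle exact.
* **Dual projection.** Each lumbar-labeled cell is dual with a
  region-specific probability; dual cells appear in both channels at the
  same location, the cervical copy jittered by an isotropic Gaussian of
  sd 0.5 µm — far below the 4 µm matching radius, so matching is testable
  with and without noise.
* **Intensities.** Log intensities are Gaussian per channel with
  cross-channel correlation $\rho$ (default 0.6) in dual cells, and the
  cervical intensity of dual cells is multiplied by a dimming factor in
  (0, 1] (default 0.5). This reproduces the two signatures seen in real
  co-labeling data: positively correlated brightness under co-injection,
  and systematically dimmer cervical label in dual-projecting cells.
* **Injury.** A severity maps to a per-region sparing fraction; injured
  animals' cells are thinned binomially, a dual cell surviving or dying as
  a unit.
* **Behavior.** The locomotor score is $9\times$ the weighted realized
  sparing of designated regions plus Gaussian noise, clipped to $[0, 9]$
  (optionally quantized to the 0.5 steps of the real scale). The real
  scale is ordinal and nonlinear; a monotone continuous stand-in is enough
  for rank-based association and two-group screening, which is all the
  package infers from it.

The default design (`default_cohort_design()`) emulates a dual
cervical/lumbar labeling study across eleven supraspinal populations
(corticospinal, red nucleus, gigantocellular, lateral hypothalamus,
paraventricular hypothalamus, pedunculopontine, medullary and pontine
reticular, vestibular, solitary, deep cerebellar): roughly 24,000
lumbar-labeled nuclei per brain, a brain-wide lumbar-projection index near
27%, region co-label rates from 8% to 55%, a 65.8% co-detection baseline
in co-injected controls, and mild/moderate/severe arms sparing roughly
55%/25%/0.1% of label, with recovery coupled to the pedunculopontine
region. Arm sizes (4 dual-labeled, 3 co-injected, 3/6/3 injured) match the
scale of such studies.

What the generator does **not** emulate: registration error fields,
optical clearing artifacts, autofluorescence, classifier false positives,
and anisotropic within-region density. Passing tests therefore demonstrate
correctness of the quantification given registered points, not robustness
to upstream imaging failures.

## Spot detection and dual-label matching

The commercial spot functions used in practice are unpublished, so
`detect_spots()` is an explicit classical stand-in, not a byte-level
replica: difference-of-Gaussian band-pass filtering with per-axis scales
set from the 4 µm (XY) and 8 µm (Z) spot diameters
($\sigma = d / 2\sqrt{2}$, second scale $1.6\sigma$), local-maximum
extraction tolerant of plateau ties, a minimum separation of one spot
diameter (anisotropic ellipsoid), and a threshold applied to the raw image
intensity at the peak, which is also the intensity the spot reports.

`match_dual()` accepts candidate pairs within the distance threshold
greedily in ascending distance order, ties broken by lowest index, each
nucleus used at most once. The default metric is plain Euclidean at 4 µm,
following the stated measurement convention; an anisotropic option divides
z offsets by the 8/4 diameter ratio first, since axial localization is
twice as coarse. Greedy matching is a maximal, not necessarily maximum,
matching; at realistic nucleus densities (well-spaced nuclei, a few
candidates per thousand cells) the test suite shows it equals the
maximum-cardinality oracle on every random instance tried.

The dropout analysis re-runs matching after keeping only the brightest
fraction $q$ of cervical nuclei (ranked by intensity, ties by index;
$\lfloor qn \rfloor$ kept). Because dual cells carry dimmer cervical
label, they drop out first and the apparent dual-innervation rate falls
monotonically. Under the default dimming (0.5 on a lognormal with
$\sigma_{\log} = 0.5$), retaining the brightest 20% removes ~98% of the
apparent dual rate — stronger than the ~80% figure published for
corticospinal neurons, whose intensity separation is presumably narrower;
the point the analysis establishes, that estimated dual-innervation rates
depend steeply on detection sensitivity, is threshold-free.

## Indices

The **lumbar-projection index** of a region is lumbar count over
lumbar + cervical count. It is computed per animal and then averaged with
its SEM, matching the convention of reporting mean ± SEM across N animals;
the brain-wide value uses each animal's brain-wide totals (averaging
region indices instead is available as an option, since the published
description does not fix this choice). Regions with zero total in an
animal are undefined for that animal, and the index is invariant to
uniform rescaling of both channels.

The **sparing index** expresses an injured animal's per-region count as a
percentage of the mean count in uninjured reference animals (reference
mean = 100%). Zero-reference regions are flagged and excluded, as are
regions on the exclusion list. When injured counts are drawn from the
reference distribution the index averages 100%, which the suite verifies.

The **bridge fraction** measures astrocytic continuity across a lesion:
binarize the GFAP image at a threshold, label 8-connected components
within the lesion band, call a column bridged when a component touching
both band edges passes through it, and report bridged columns over cord
width. The published measurement is a width ratio only; the column-path
connectivity rule is this package's operationalization, chosen so the
answer is invariant to intensity rescaling on either side of the threshold
and exact (±1 column quantization) on sections with known bridge spans.

## Group statistics

Recovery screening splits animals on the locomotor score (≥ 5 consistent
stepping, ≤ 3.5 impaired, the gap excluded; both thresholds
configurable), then compares spared counts per region between groups.
Unequal group sizes make a paired test inapplicable, so Welch two-sample
tests are used. Significance is controlled by Bonferroni's rule applied as
a threshold adjustment — a region is flagged when $p < \alpha/m$ — with
$m$ counting only regions actually tested (≥ 2 animals per group,
non-excluded), and the report includes the group-separation gap,
min(high) − max(impaired). With 26 regions at $\alpha = 0.05$ the
threshold is 0.0019231. Simulation in the test suite confirms family-wise
error ≤ 0.05 under the global null; the same simulation shows that a
3-sd effect with 6 vs 6 animals is flagged in only about two-thirds of
replicates at this threshold — regions can carry substantial effects and
still fail a Bonferroni screen at these sample sizes, which is the
statistical reality of the design rather than a defect of the
implementation.

ANOVA with Sidak-corrected post-hoc comparisons
($p_{adj} = 1 - (1-p)^k$, pooled residual variance) covers the
condition-comparison layouts: one-way across severity arms and two-way
region × condition. The two-group one-way case collapses to the pooled
t test exactly, and a hand-computed sums-of-squares oracle pins the
balanced two-way decomposition. Zero residual variance is flagged
degenerate rather than producing spurious infinities. Region-wise
sparing–behavior association uses Spearman rank correlation, which is
indifferent to the monotone-but-nonlinear mapping between sparing and the
behavioral scale.

## Numerical and scale choices

Problem sizes were chosen so the whole test suite runs in a few minutes:
toy atlases of 20–80 voxels per axis at 25 µm, cohorts of 2–60 animals
with hundreds of nuclei per region for unit tests, and n = 30 animals for
parameter-recovery checks. The acceptance script runs the full
study-sized default design (≈ 690,000 nuclei across 19 animals) in about
a minute. Fixed seeds make every simulated quantity reproducible;
identical configuration and seed give byte-identical outputs, which the
suite checks on serialized cohorts and pipeline reports.

Degenerate inputs are handled by flags, not silent drops: unassigned and
out-of-bounds points are tallied, zero-denominator indices are marked
undefined, constant vectors yield undefined correlations, and skipped
regions are named in screening output.

## Known limitations

* The spot detector approximates, and is not calibrated against, the
  proprietary tools used to produce published counts.
* Greedy matching can in principle fall below the optimal pair count in
  pathological high-density geometries; it is exact at the densities of
  well-spaced nuclear labels.
* The behavior model is a monotone stand-in; no longitudinal (weekly)
  score modeling is attempted.
* Real-atlas mode expects a registered annotation volume and structure
  graph; the package neither downloads atlases nor registers images.
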