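---
title: "Spatial immune profiling of mIF cell tables: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune profiling of mIF cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifspat)
```

# What this package models

Multiplex immunofluorescence (mIF) panels stain one tissue section for many
protein markers at once. After spectral unmixing, cell segmentation and
per-marker scoring — all upstream of this package — the image-analysis
system exports *cell tables*: one row per nucleated (DAPI+) cell with its
x/y coordinates inside a rectangular region of interest (ROI, here a
931 × 698 µm field scanned at 20×, 0.5 µm/pixel), a tissue-compartment
label (tumor-epithelial nests vs tumor-stroma), and 0/1 positivity flags
for the eight panel markers: panCK (malignant/epithelial lineage), CD3
(T cell), CD8 (cytotoxic), Foxp3 (regulatory), CD68 (macrophage), KI67
(proliferation), and the checkpoint pair PD-1/PD-L1.

`mifspat` is the downstream analysis: it consolidates per-marker exports
into one table, calls boolean co-expression phenotypes, computes
compartmentalized densities, measures malignant-cell-to-immune-cell
distances with a median-radius close/far rule, and classifies the
tumor–T-cell geometry of each ROI as **mixed** or **unmixed** by comparing
the empirical nearest-neighbour G function with the theoretical Poisson
curve. Because cohort-level cell data of this kind are rarely deposited,
the package ships a synthetic tumor-microenvironment generator with known
ground truth; every analysis stage is tested against it.

# Coordinate consolidation and phenotyping

Image analysis is typically run once per marker, so the same physical cell
appears in several exports. `merge_marker_calls()` joins each
marker-positive event to the nearest cell of the DAPI *spine* (the
all-nucleated-cells table) within a tolerance, in the same ROI.

* **Tolerance default: 0.5 µm**, one pixel at the stated resolution. The
  merge is described upstream only as "by X and Y coordinates"; one pixel
  is the smallest displacement a re-segmentation can introduce, and an
  exact-coordinate join is the degenerate case (tolerance 0 still matches
  identical coordinates).
* Matching is one-to-nearest; exact distance ties resolve to the smallest
  `cell_id`, so runs are reproducible. Unmatched events are dropped but
  counted in a QC attribute — the merge never invents or loses spine cells.

`call_phenotypes()` evaluates a registry of boolean rules
(`positives` all on, `negatives` all off, other markers free). The shipped
registry (`phenotype_registry()`) has 26 rows — 4 malignant, 18 T-cell, 4
macrophage. Two points matter for interpretation:

* **Rules are nested, not exclusive.** A CD3+CD8+PD-1+ cell contributes to
  `CD3+`, `CD3+CD8+` and `CD3+CD8+PD-1+` alike; densities of sub-rules can
  therefore never exceed their parent rule (a tested invariant).
* **Only the regulatory rows constrain a negative marker** (`CD8-`), since
  Foxp3 regulatory T cells are defined by the absence of CD8; all other
  rows leave unlisted markers unconstrained.

Cells positive for more than one lineage marker (e.g. panCK and CD3 —
usually a segmentation artifact) are resolved by a configurable priority,
default panCK > CD3 > CD68, and always QC-flagged. Case-level PD-L1 status
uses the strict rule: positive iff the PD-L1+ fraction of panCK+ cells
**exceeds** 1% ("greater than", so exactly 1% is negative).

# Densities

Per ROI and compartment, density = matching-cell count ÷ compartment area
(mm²); the per-case value is the **unweighted mean over the case's ROIs**
(an area-weighted mean is a one-line change, but the plain average of
per-ROI densities is what report consolidation tools produce). The
`combined` compartment uses epithelial + stroma counts over summed areas.

When tissue-category areas are not exported, compartment areas are
estimated by apportioning the ROI area by cell count. This is exact when
cell density per unit tissue is equal in both compartments and biased
otherwise; measured areas override it whenever available. ROIs with a
zero/unknown compartment area are excluded from that compartment's average
with a warning — never silently scored 0.

The epithelial-vs-stroma comparison is the **two-sided Wilcoxon rank-sum
test as named**, although the design is paired by case; a paired
signed-rank test would be more powerful, but the comparison stage
reproduces the named method and flags the choice here. The exact null is
used when both groups have ≤ 12 values and no ties; otherwise the normal
approximation with tie correction (noted in the output). Kruskal–Wallis
(> 2 groups) and chi-square/Fisher (categorical, Fisher when any expected
count < 5) are exposed as thin wrappers.

Staining-reproducibility QC for tissue microarrays correlates per-core
marker percentages (of DAPI+ cells) between staining runs with Spearman's
rho; the Bonferroni family is **all marker × time-point-pair tests in one
run** (24 tests for 8 markers × 3 pairs), significance at adjusted
p < 0.05. Constant percentage vectors leave rho undefined and are reported
as such rather than coerced.

# Distances, the overall radius, and close/far

"Distance from malignant cells to phenotype X" is directional: for every
panCK+ reference cell, the distance to its *nearest* X cell; the summary
is the median over reference cells. The direction follows the proximity
table's reading "from malignant cell to immune cell"; an all-pairs-median
mode (`method = "allpairs"`) is provided because a raw distance-matrix
formulation is ambiguous between the two.

* Distances never cross ROI boundaries (ROIs are disjoint physical
  fields). Per case, reference-cell nearest-neighbour distances are pooled
  across ROIs *before* taking the median, so every reference cell counts
  once regardless of how full its ROI is.
* The **overall radius** is the median over the (case × target phenotype)
  grid of median distances in the panCK+ stratum — a median of medians,
  the simplest aggregation consistent with a single cohort-level radius.
  Computing it per case first and medianing those is a trivial variant;
  the pooled grid is the default and the documented one.
* A phenotype is **close** when its median distance ≤ radius (ties are
  close by the stated "equal or less" rule), else **far**.

The PD-L1 stratification repeats the computation with reference = all
panCK+, panCK+PD-L1−, and panCK+PD-L1+ cells; the first stratum is always
the union of the other two, and empty strata yield "not evaluable" (`NA`)
rather than zeros.

# The G function and the mixed/unmixed call

For reference pattern R and target pattern T on one ROI,

* empirical G: `G_emp(r)` = fraction of R whose nearest T lies within r;
* theoretical Poisson G: `G_pois(r) = 1 − exp(−λπr²)` with λ = observed
  target count ÷ ROI area ("the same intensity as the observed pattern");
* deviation: `100 × (G_emp − G_pois)` in percentage points, on a default
  grid of 0–200 µm in 1 µm steps (200 µm being the largest swept
  neighbourhood radius).

The classification: **mixed** when the deviation stays within ±10 over the
whole grid; **unmixed** when it exceeds +10 anywhere; when it only falls
below −10 the call is **indeterminate** — the published rule names no
branch for curves running *below* the Poisson curve. Three design notes:

* **Units of "±10".** The threshold is unitless in its source; the only
  reading that keeps both bounds reachable on a probability-valued curve
  is percentage points of G, i.e. the band |G_emp − G_pois| ≤ 0.10. Both
  thresholds are configurable.
* **Polarity.** Ecologically, a cross-G *above* Poisson means the target
  is closer to the reference than chance (attraction), so "deviation >
  +10 = unmixed (segregated)" reads inverted. The rule is implemented
  literally; in practice segregated geometries drive the deviation
  strongly *negative*, land in the indeterminate branch, and are therefore
  still cleanly distinguished from mixed — the recovery tests rely only on
  "mixed" vs "not mixed".
* **No edge correction by default.** The empirical G is the raw CDF; a
  reduced-sample (border) correction is available via
  `correction = "border"`, which at each r keeps only reference cells at
  least r from the ROI boundary (unbiased, but higher variance at large r).

ROI-level calls aggregate to a case by **majority vote, ties
indeterminate**. `phenotype_pattern_profile()` runs the whole machinery
per phenotype (reference = panCK+) and emits long-format curves plus the
per-ROI/per-case call tables.

# The synthetic generator

`simulate_landscape()` emulates what the pipeline consumes, not pixels:

| parameter | default | rationale |
|---|---|---|
| window | 931 × 698 µm | the 20× high-magnification field |
| cohort | 12 cases × 10 ROIs | the study design the pipeline targets |
| nests | 5 discs of radius 80 µm | "cohesive nests" as uniform discs, the simplest geometry |
| tumor intensity | 3200 cells/mm² in nests | keeps nest purity ≥ 85% (the ROI-selection rule) even under full immune mixing; within the plausible per-case range |
| immune intensity | CD3 310, CD68 150 /mm² | ≈ 200 T cells and ≈ 100 macrophages per ROI, matching low-infiltrate tumors and the ≥ 200-cells-per-type preset floor |
| PD-L1 on tumor | 25% | a clearly PD-L1-positive case under the 1% rule |
| co-expression | see `default_coexpression()` | chosen so phenotype densities fall inside published cohort ranges; CD8/Foxp3 subtypes mutually exclusive, other markers independent |

`mixing` is the ground-truth dial: 1 scatters immune cells uniformly
(mixed; they enter nests freely), 0 excludes them from every nest dilated
by a 100 µm margin (unmixed). Marker flags are independent across cells
given lineage — the generator deliberately has *no* spatial
autocorrelation of marker state beyond geometry, because no analysis stage
assumes any. Per-ROI random substreams are derived as
`(seed + 7919·case + 104729·roi) mod (2³¹−1)`, so ROIs are independent yet
the whole cohort is reproducible from one seed.

What the generator does **not** emulate — segmentation error, intensity
thresholding noise, spectral bleed-through, irregular nest shapes, tissue
folds — bounds what a green test establishes: correctness of the
*analysis* given well-formed cell tables, not robustness to upstream
imaging artifacts.

# Numerical choices and degenerate inputs

* Coordinates are µm everywhere internally; pixel inputs are converted on
  read (0.5 µm/pixel default). Round-trips are exact to 1e-6 µm.
* Nearest-neighbour queries run in compiled code as an exact O(n·m) scan
  (no approximate index); they match a brute-force R oracle bitwise.
* Empty point sets propagate "not evaluable" (`NA` or an explicit error),
  never 0: a phenotype absent from an ROI is missing data, not distance 0.
* QC on an ROI without an epithelial compartment reports that flag instead
  of dividing by zero.
* All-identical comparison vectors give p = 1 with a degenerate-data note.
* Even-n medians are the mean of the central pair (the R default).

# Known limitations

* **Per-ROI pattern calls are noisy at realistic cell counts.** A mixed
  call requires the empirical G to track the Poisson curve within 0.10
  everywhere; by Kolmogorov–Smirnov arithmetic that needs ≥ ~185
  *effectively independent* reference cells, so with 130–320 (often
  spatially correlated) references a genuinely uniform landscape is called
  mixed in only ~75–85% of replicates, the rest splitting into the
  indeterminate/unmixed branches by chance. Segregated landscapes, by
  contrast, are essentially never called mixed. Treat "mixed" as a
  specific but imperfectly sensitive label at ROI scale, and prefer the
  case-level majority vote.
* The compartment-area estimate from cell counts is a surrogate; supply
  measured tissue-category areas when the image software exports them.
* The rank-sum compartment comparison ignores the pairing by case (by
  design, to reproduce the named method).
* The mixed/unmixed rule evaluates deviation extrema only; no
  hidden-state or curve-intersection modelling is attempted, and K/L/pair
  correlation functions are out of scope.
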