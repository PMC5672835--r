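---
title: "Methods: resource selection, K-select and Mahalanobis suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource selection, K-select and Mahalanobis suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habselect)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, and the design choices made where the
methodology is genuinely open. It states no empirical result that the
test suite does not itself compute.

## The analysis unit

All analyses run at the **resource unit** (RU) grain: a coarse raster cell
(default 90 m, i.e. an aggregation factor of 3 over 30 m input rasters)
carrying one value per eco-geographical variable (EGV). Categorical land
cover is expanded into per-class *proportion* layers, continuous layers
are block means. Two conventions matter downstream:

- **Half-open cells.** A point on a shared cell edge belongs to the cell
  to the east (vertical edges) or south (horizontal edges). This makes
  point-to-RU assignment total and unambiguous.
- **Dominant class.** For categorical selection analyses each RU is
  labelled with its modal cover class (largest proportion; ties broken by
  the smallest class code). Selection over "habitat types" needs a
  discrete label per RU, and the modal class is the coherent
  discretization at RU grain. The per-class proportions remain available
  as continuous EGVs, so no information is discarded.

RUs whose fine cells are more than 50% nodata are dropped; otherwise
block statistics use the valid cells only. Trailing rows/columns not
divisible by the aggregation factor are dropped with a warning.

Screening: pairwise Pearson correlations with a default flag threshold of
|r| ≥ 0.7 (the conventional collinearity alarm level; configurable), a
centred and scaled PCA of the EGV table, and global Moran's I with
row-standardized rook contiguity as the spatial autocorrelation statistic
(queen contiguity optional). Cohen's kappa summarizes land-cover map
accuracy from a confusion matrix.

## Selection ratios with individual availability

Availability is animal-specific: the RUs whose centres fall inside the
animal's 100% minimum convex polygon (MCP). The centre-in-polygon rule
follows the "pixels falling inside the home range" convention; one
boundary subtlety is resolved explicitly: an RU can contain one of the
animal's relocations while its centre lies just outside the hull. Such an
RU is demonstrably available to the animal, so `hr_availability()` adds
used RUs to the availability set. This guarantees used ⊆ available, which
the estimators require.

For animal *j*, used counts \(u_{ij}\) over categories and availability
proportions \(\pi_{ij}\) give \(\hat w_{ij} = (u_{ij}/u_{+j})/\pi_{ij}\),
and the log-likelihood statistic
\(\chi^2_{Lj} = 2\sum_i u_{ij}\ln(u_{ij}/(u_{+j}\pi_{ij}))\) (zero counts
contribute zero). Pooled over animals,
\(\hat w_i = \sum_j u_{ij} / \sum_j u_{+j}\pi_{ij}\) over the animals for
which category *i* is available; \(\chi^2_L = \sum_j \chi^2_{Lj}\) with
\(df = \sum_j (I_j - 1)\), where \(I_j\) counts the categories available
to animal *j* — so the global df need not be a multiple of the animal
count when some category is absent from some home range.

**Interval estimation.** The variance of \(\hat w_i\) is estimated from
among-animal variability: \(\mathrm{var}(\hat w_i) = s^2(\{\hat
w_{ij}\}_j)/K_i\) over the \(K_i\) animals with \(\pi_{ij} > 0\), with a
Bonferroni-adjusted normal quantile \(z_{\alpha/(2I)}\) across the \(I\)
categories. This estimator is distribution-free and honest about
between-animal heterogeneity; its cost is wide intervals when few animals
contribute or when availability differs strongly among them (visible in
the README example). A category is reported *selected* when the interval
lies above 1 and *avoided* when it lies inside (0, 1). Animals with fewer
than 5 used locations are flagged, not excluded.

## K-select marginality

EGVs are standardized to mean 0, sd 1 over all study-area RUs before any
marginality computation: the squared norm of a difference of means is
meaningless across variables measured in metres, degrees and proportions.
Each animal's marginality vector is
\(m_k = \bar z(\text{used}_k) - \bar z(\text{avail}_k)\); its squared
norm measures selection strength. The weighted non-centred eigenanalysis
of \(C=\sum_k w_k m_k m_k^\top\) yields axes whose eigenvalues sum to the
weighted mean squared marginality (asserted to 1e-10 in the tests), so
"percent of marginality explained" is well defined. Animal weights are
uniform by default; weighting by relocation count is available
(`weights = "n_used"`) since reference implementations differ on this
point.

**Randomization tests.** The null of random habitat use re-draws each
animal's used RUs *without replacement* from its availability
(equi-probable allocation) and recomputes \(\lVert m^*\rVert^2\) (or, for
the common-structure test, the first eigenvalue with every animal re-drawn
simultaneously). The p-value uses the add-one estimator
\((1+b)/(N+1)\), whose floor at \(N=10{,}000\) is \(1/10001 \approx
0.000099\); ties count as exceedances (conservative). Because the null
draws without replacement, the observed used sample must itself be a set
of RUs: the pipeline therefore uses each animal's *distinct* visited RUs
for K-select. (`marginality()` itself accepts multisets — repeat visits
weight the used mean — for workflows that want utilization weighting.)
Randomization is per-animal availability by default; passing a global RU
set to `marginality_randomization()` gives the study-area-wide variant.
Per-animal significance is reported against the Bonferroni level
\(\alpha/K\).

## Spatial thinning

Before suitability fitting, settled-period relocations are deduplicated
and thinned until the Clark–Evans index
\(R = \bar d_{NN} \cdot 2\sqrt{n/A}\) reaches 1. The reference area *A*
is the animal's 100% MCP area — the only per-animal window the workflow
constructs — and no edge correction is applied (the plain index).
"Removing records from the closest neighbour" is ambiguous as a rule; the
implemented reading is a deterministic greedy step: find the closest
retained pair, delete the member whose removal yields the larger mean
nearest-neighbour distance (ties: the higher index), recompute R. Removing
both members of each pair was rejected because it can overshoot past
R = 1. The stopping rule is one-sided, \(R \ge 1-\text{tolerance}\)
(default tolerance 0.01 as an API default; the pipeline uses 0.05 at its
small problem sizes), because clustered telemetry approaches 1 from
below; a floor of `min_points` retained locations guards against
degenerate windows, and failure to reach the target is flagged
(`converged = FALSE`), never silently ignored.

## Mahalanobis suitability and evaluation

The niche model is the mean μ and sample covariance Σ of the EGVs at the
thinned settled locations, pooled across animals, on the **original**
variable scales (D² is scale-equivariant, so standardization is
unnecessary here). Each RU's dissimilarity is
\(D^2 = (x-\mu)^\top\Sigma^{-1}(x-\mu)\), mapped to suitability by the
\(\chi^2_p\) survival function (p = number of EGVs) under the multivariate
normality assumption — an assumption that class-proportion EGVs only
approximate; the evaluation curve below is the empirical check on the
resulting map.

**Conditioning.** Singularity is judged on the correlation matrix (a
scale-free criterion; condition number above 1e8 errors). The optional
ridge is applied on the correlation scale, \((R+\varepsilon I)/(1+
\varepsilon)\), rescaled by the variances — a unit-aware shrinkage.
`fit_niche()` ships with the ridge off; the pipeline defaults to a light
\(\varepsilon = 10^{-4}\) because cover-class proportions are exactly
compositional inside home ranges containing no water or settlement cells,
making Σ singular by construction. EGVs constant at the fitting locations
are dropped with a message.

**Evaluation.** Suitability in [0, 1] is cut into 20 fixed classes of
width 0.05 (the fixed-class variant, not the moving-window one). With
\(E_i\) the relative area and \(P_i\) the share of evaluation points in
class *i*, \(F_i = P_i/E_i\); classes with \(E_i = 0\) are excluded.
\(F_i = 1\) marks random use. The reclassification threshold is the lower
bound of the first class, scanning upward, from which F stays above 1 —
the "first sustained upcrossing". A last-upcrossing alternative was
considered and rejected as the default because it discards genuinely
suitable mid-range classes when the curve is noisy. The Boyce index is
the Spearman rank correlation of \(F_i\) with class rank (the adjusted R²
of the least-squares line of F on rank is reported alongside); it is
returned as flagged `NA` when F is constant. Evaluation points default to
the same thinned locations that fit the model — the presence-only
workflow without an independent sample — so the index is optimistic; the
pipeline's `holdout` fraction enables honest evaluation.

## The synthetic generator

`generate_landscape()` / `generate_telemetry()` create studies with known
ground truth. The landscape: per-class Gaussian-smoothed noise fields with
an argmax giving patchy cover (regenerated, then rejected with an error,
if any class is absent — in the degenerate limit one class covers the
whole grid); a smooth elevation surface spanning 166–546 m with its
gradient-magnitude slope in degrees; an NDVI-like index in [−0.19, 0.5];
a meandering river corridor plus waterholes and a few settlement blobs,
overlaid as cover classes of their own *and* turned into exact Euclidean
distance layers; a central core zone with a distance layer that is 0
inside the core (the in-core convention chosen for distance-from-zone
variables); and a core/buffer zone raster. Water and settlement are
deliberately *not* proportion EGVs, mirroring studies where such classes
enter as distance layers; this also keeps the EGV proportions from being
exactly compositional.

Telemetry follows an exponential (log-linear) resource-selection
function, the standard RSF family: within each animal's home-range disc,
used RUs are drawn with probability \(\propto \exp(\beta^\top z)\) on
standardized EGVs, and each relocation is placed uniformly inside its RU
cell (so a point can overshoot the disc by at most the RU half-diagonal).
β may differ between the exploratory and settled periods, emulating a
behavioural contrast between a wandering phase and established home
ranges. One root seed drives everything; per-animal child seeds are
derived as `seed + 9973 * animal_index`, so single-animal regeneration is
stable under changes to the roster.

The defaults emulate a reserve-scale carnivore study: 9 animals, two
periods, ~11,000 relocations in total, 16 EGVs of which 10 are
cover-class proportions, selection concentrated on a few cover classes
(settled: strong selection for one forest-like class, avoidance of
settlement proximity; exploratory: weaker, water-oriented selection). The
spatial geometry is scaled down (a 5.4 km landscape with ~0.65 km
home-range radii rather than tens of km) to keep full-pipeline runs
interactive; the test suite runs on 90–150-cell grids with 2–8 animals
and 80–500 relocations per animal-period, sizes chosen so the statistical
checks (null calibration with 200 replicates, parameter recovery over 20
replicates, a 10,000-draw randomization) are informative at desk scale.

What the generator does **not** emulate — and hence what passing tests do
not show about field data: movement autocorrelation (step-selection or
Ornstein–Uhlenbeck dynamics; relocations are conditionally independent
draws), GPS fix error and habitat-dependent fix rates, classification
error in the cover map, temporal drift in availability, and behavioural
interactions between animals. The thinning stage therefore removes
sampling-design clustering in the tests, not true serial correlation.

## Degenerate inputs and numerical conventions

- MCPs require ≥ 3 non-collinear points; hulls are stored as closed
  counter-clockwise rings and areas computed by the shoelace formula.
- A point on a polygon boundary counts as inside (tolerance 1e-9,
  edge-length scaled).
- `selection_ratios()` treats a used-but-unavailable category as a data
  error naming the animal and category, not as a zero to patch over.
- Constant EGV columns are excluded with warnings (correlation, PCA,
  standardization) or errors (an all-constant table).
- Floating-point outputs are written with 10 significant digits so reruns
  diff cleanly; manifests record MD5 checksums per artifact.
- All randomized procedures take explicit seeds; equal values in
  randomization tests count against the alternative.

## Known limitations

- The among-animal variance for pooled selection ratios needs several
  animals with comparable availability to give useful intervals; with
  K ≤ 3 or strongly heterogeneous availability the Bonferroni intervals
  are honest but wide.
- The χ² mapping of D² to suitability leans on multivariate normality;
  heavily skewed EGVs would call for transformation before fitting.
- Greedy thinning is O(n²) per removal via a maintained distance matrix,
  comfortable for thousands of relocations per animal but not for
  millions.
- The Fi threshold is undefined when no class sustains F > 1;
  `reclassify_suitability()` then refuses rather than guessing.
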