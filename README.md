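# habselect

Fine-scale habitat selection and habitat suitability analysis for
radio-collared wildlife, at the resource-unit (RU) grain.

Telemetry studies of large carnivores typically ask two connected
questions: *which habitats does each animal select, relative to what is
available to it?* and *which parts of the landscape are suitable for the
population?* `habselect` implements a complete, testable workflow for both,
aimed at spatial ecologists working with use-availability designs:

- **Resource units.** Co-registered eco-geographical variable (EGV) rasters
  at fine grain (e.g. 30 m) are block-aggregated to RUs (e.g. 90 m):
  categorical land cover becomes one proportion layer per class, continuous
  layers (elevation, slope, greenness, Euclidean distances to water,
  settlements, a core zone) become block means. Screening tools: Pearson
  correlation, PCA, global Moran's I, and Cohen's kappa for map accuracy.
- **Selection ratios** (Manly's selectivity, individual-availability
  design). For animal *j* and habitat category *i*, the ratio is
  ŵᵢⱼ = (uᵢⱼ/u₊ⱼ)/πᵢⱼ with each animal's own availability πᵢⱼ taken from
  the RUs inside its 100% minimum convex polygon. The pooled ratio is
  ŵᵢ = Σⱼuᵢⱼ / Σⱼu₊ⱼπᵢⱼ, tested with the log-likelihood chi-square
  χ²_L = 2ΣᵢΣⱼ uᵢⱼ ln(uᵢⱼ/(u₊ⱼπᵢⱼ)), df = Σⱼ(Iⱼ−1), with Bonferroni
  confidence intervals across categories.
- **K-select.** Each animal's marginality vector m = z̄(used) − z̄(available)
  on standardized EGVs; the weighted non-centred eigenanalysis of
  C = Σₖ wₖ mₖmₖᵀ summarizes selection common to the population, and
  randomization tests (used RUs re-drawn without replacement from each
  animal's availability, add-one p-value (1+b)/(N+1)) assess individual
  marginality and the first eigenvalue.
- **Spatial thinning.** Duplicate removal, the Clark–Evans aggregation
  index R = mean NN distance / (2√(n/A))⁻¹, and deterministic greedy
  thinning of the closest pairs until R reaches 1 (spatial randomness).
- **Suitability.** Mahalanobis D² = (x−μ)ᵀΣ⁻¹(x−μ) from the mean habitat at
  the thinned settled locations, mapped to a p-value by the χ²ₚ survival
  function; evaluation by the predicted-to-expected curve over 20
  suitability classes, Fᵢ = Pᵢ/Eᵢ, the Boyce index (Spearman rank
  correlation of Fᵢ with class rank), and binary reclassification at the
  Fᵢ = 1 threshold with per-zone (core/buffer) area summaries.
- **Synthetic studies.** A generator for patchy landscapes and telemetry
  from an exponential resource-selection function with known coefficients,
  so the full pipeline can be validated end to end against ground truth.

Rasters are read and written as plain-text ESRI ASCII grids (`.asc`);
polygons as GeoJSON; tables as CSV; configs as YAML.

## Worked example

Simulate a four-animal study and run every stage (EGV aggregation, home
ranges, selection ratios, K-select, thinning, suitability, evaluation):

```r
library(habselect)
cfg <- synthetic_config(seed = 42, grid_rows = 120, grid_cols = 120,
                        n_animals = 4, points_per_animal_per_period = 200,
                        home_range_radii = 600)
run_pipeline(cfg, "demo", randomization_n = 1000, thin_min_points = 30)
```

The settled-period selection table (`demo/selection_ratios.csv`) shows the
generator's preference for cover class 2 recovered as the top ratio
(pooled ŵ = 3.47; its interval is wide here because only four animals
contribute to the among-animal variance):

```
 category     w   ci_low ci_high classification
  class_2 3.471 -25.9861  32.928   proportional
  class_6 0.233  -0.0372   0.504   proportional
  class_3 0.221       NA      NA   proportional
settled chi2 = 2391.77, df = 24, p = 0
```

The pooled χ²_L = 2391.77 on 24 df rejects proportional use overall. The
K-select first axis carries 69.5% of the mean marginality (eigenvalue
1.567), and every settled animal's marginality is significant at the
Bonferroni level 0.0125:

```
  period axis eigenvalue percent
 settled    1      1.567    69.5
 settled    2      0.353    15.7

    period          animal_id observed  p_value bonferroni_alpha
   settled                A04     3.41 0.000999           0.0125
   settled (first eigenvalue)     1.57 0.000999           0.0125
```

Evaluation of the D² suitability map (`demo/evaluation.json`): Boyce
Spearman r = 0.58, Fi-threshold 0.65, and 10.7% of the core zone vs 0.6%
of the buffer classified suitable — the generator places the selected
habitat inside the animals' core-area home ranges, so the contrast is the
expected one.

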