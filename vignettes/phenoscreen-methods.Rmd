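---
title: "Methods: quantitative analysis of single-cell morphometric screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of single-cell morphometric screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

`phenoscreen` implements the statistical machinery of a genome-wide,
image-based phenotypic screen of a bacterial single-gene deletion library:
thousands of strains, each summarised from a few hundred segmented cells
into one feature vector, referenced against a panel of wild-type (WT)
replicates, and then mined for phenotype structure. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the method left room.

## The snapshot cell-cycle model

Everything cell-cycle-related rests on one steady-state assumption: in an
exponentially growing population with stable age structure, the density of
relative cell age $a \in [0,1]$ (0 = birth, 1 = division) is

$$ f(a) = 2\ln 2\; 2^{-a}, $$

so newborns are twice as frequent as dividing cells. Two consequences are
used throughout:

* **Rank-to-age.** If $F$ is the fraction of cells with length at or below
  a given cell's, that cell's relative age is
  $\mathrm{age}(F) = -\ln(1 - F/2)/\ln 2$ (`age_from_rank()`). The mapping
  is rank-based, hence invariant to length units and to any monotone
  distortion of growth in size.
* **Fraction-to-timing.** The fraction of cells older than age $a$ is
  $2^{1-a}-1$; inverting it, an event observed in a fraction $p$ of cells
  occurred at relative age $T = 1 - \log_2(1+p)$
  (`relative_event_timing()`). A single snapshot therefore yields the
  relative timing of nucleoid separation (from the fraction of cells with
  two nucleoids) and of constriction onset (fraction with constriction
  degree above 0.15, the threshold used for the event curves; it is a
  parameter everywhere it appears).

Only *relative* timings are identifiable — absolute durations would need an
extra clock — and only population averages: single-cell timing variability
is invisible to a snapshot. The steady-state assumption is not corrected
for; populations far from balanced growth will bias both timings.

`coupling_stats()` adds the two coupling statistics: `rho_cd`, the Pearson
correlation between cell and nucleoid constriction degrees across
constricting cells, and `cdn_c0`, the mean nucleoid constriction degree in
the *onset band*. The onset band is operationally defined here as the
lowest decile of strictly positive cell constriction degrees (width
configurable); the source analysis did not define it operationally, so this
is the package's choice.

## The synthetic screen generator

Because the original raw screen is not reproducible at desk scale, every
stage is validated against a generator with known ground truth
(`strain_spec()`, `screen_truth()`, `generate_screen()`). It emulates:

* steady-state ages (`sample_ages()`, exact inverse CDF);
* exponential single-cell elongation `length = birth_length * 2^age` with
  lognormal noise; the WT per-age length CV of 0.11 is the experimentally
  determined value used throughout, and lognormals are parameterised by
  arithmetic mean and CV because that is how the screen reports spreads;
* age-thresholded nucleoid separation (`t_nuc`) and constriction onset
  (`t_const`), with a linear constriction-degree ramp to 1 at division —
  downstream analysis only uses the binary "degree > 0.15", so the ramp
  shape is inert;
* division ratios drawn Normal(0.5, `sigma_dr` = 0.03) truncated to (0, 1);
* spherocylinder geometry (below) plus intensity-type features with
  realistic noise for the curation classifier;
* Gompertz growth curves (default: lag 120 min, maximal specific growth
  rate 0.0096 / min, i.e. a ~72 min doubling time at 30 °C, saturation near
  OD 0.8 from a 0.01 inoculum, Gaussian OD noise 0.003) sampled every
  5 min for 16 h;
* per-strain imaged cell counts Normal(291, 116) truncated at 30, matching
  the per-strain counts of the reference screen;
* multiplicative per-plate biases on linear dimensions (lognormal CV 0.02)
  so the plate correction has something to correct.

The defaults `birth_length` 2.0 µm, `mean_width` 0.9 µm, `width_cv` 0.04,
`t_nuc` 0.55, `t_const` 0.75, `nucleoid_area_ratio` 0.35 are plausible
WT-like values and are synthetic, not measurements.

Planted phenotypes are expressed in *WT standard-deviation units*: the
generator first simulates all WT replicates, measures the empirical
replicate spread of each leverable feature, and then moves the mutant's
generative parameters so the target feature shifts by the requested number
of those SDs. An island is a group of mutants sharing offsets (±0.5 SD of
member-to-member jitter). This keeps "a +6 SD length mutant" meaningful
regardless of population size or noise settings.

What the generator does **not** emulate: segmentation artefact physics
(corruptions in `corrupt_cells()` are stylised failure modes), DAPI
photophysics, overlapping replication forks, temporal drift during imaging,
or correlated biology between features beyond what geometry induces.
Passing tests on synthetic screens therefore demonstrates the correctness
of the statistical machinery under the stated model, not the biology of any
real screen.

`simulate_length_mixture()` reproduces the stage-masking construction: the
population length distribution is the age-weighted sum of lognormal
per-age distributions at 100 equidistant ages (trapezoid weights on
$2^{-a}$), with a separate CV above age 0.8 (the "constricting" stage).
Because the age spread alone contributes a length CV of about 0.20, a
four-fold change of the late-stage CV moves the population CV by only
~9 % — the reason stage-specific CVs are screened separately.

## Geometry and the 26 features

Cells are modelled as spherocylinders: projected area
$A = w(l-w) + \pi w^2/4$, perimeter $P = 2(l-w) + \pi w$, volume
$V = \pi w^2 (l-w)/4 + \pi w^3/6$, surface $SA = \pi w (l-w) + \pi w^2$.
The source text never states the 3D formulas; the spherocylinder is the
standard rod model and is stated openly here. Circularity is
$4\pi A/P^2$ (maximum 1 for a circle) everywhere — the alternative
$2\pi A/P^2$ that appears once in the source's classifier feature list is
treated as an inconsistency and not used.

Each strain gets 19 morphological features (mean and CV of $L, W, A, P, V,
SA, SA/V$, aspect ratio $W/L$, circularity, plus the CV of the division
ratio), 5 cell-cycle features (`rel_t_nuc`, `rel_t_const`, mean nucleoid
area summed over nucleoids per cell, `rho_cd`, `cdn_c0`) and 2 growth
features (`alpha_max`, `od_max`). Division ratios are augmented with their
complements $\{r, 1-r\}$ before the CV: pole identity is unknown, so the
mean is 0.5 by construction and only the spread carries information.
Strains with fewer than 30 cells are flagged `low_n` rather than dropped.

## Growth curves

`fit_gompertz()` fits the modified (Zwietering) Gompertz model of the
log-relative density,
$\ln(\mathrm{OD}/\mathrm{OD}_0) = A \exp(-\exp(\mu e/A (\lambda - t) + 1))$,
where $\mu$ is the maximal specific growth rate (reported per hour as
`alpha_max`) and $\lambda$ the lag. Two numerical choices matter. First,
residuals are minimised on the measured OD scale with $\mathrm{OD}_0$ as a
free baseline: plate-reader noise is additive in OD, and log-scale
residuals let the noisy low-density readings dominate (with the default
noise the median $\mu$ error drops from ~9 % to ~1 %). Second, the fit is
multi-start (five data-driven initialisations; best RSS wins) because
96-well curves are noisy and the surface has local minima. Flat or barely
growing curves (max/min OD ratio < 1.2) return `converged = FALSE` instead
of an error. The saturating density `od_max` is simply the mean OD over the
final hour (`od_max()`), independent of the fit.

## Contour curation

`train_curation_model()` is a linear support-vector machine over 16
per-cell features (dimensions, volume, circularity, constriction degree,
division ratio with a missingness indicator, integrated phase and DAPI
intensities, contour intensity, width variability along the cell, nucleoid
area/variability/intensity/count), each robustly standardised by median and
iqr with the statistics frozen into the model. A linear kernel keeps the
rule auditable (the weights are inspectable via `tidy()`) and suffices for
the stylised corruption modes; classes are weighted by inverse frequency
because the balanced classification rate — the mean of sensitivity and
specificity — is the metric of record. The regularisation cost is chosen by
internal k-fold cross-validation. AUROC is computed by the midrank
Mann-Whitney statistic, which equals trapezoidal ROC integration under
ties. Models serialise to JSON and restore to bit-identical decisions.
The reference screen's own operating point (10 % cross-validated
misclassification, 84 % balanced rate, AUROC 0.94 on their images) is not a
reproduction target — their training images are not available — but the
pipeline reproduces it as a *property* on synthetic corruption:
cross-validated misclassification stays below 10 % at 30 % corruption.

## Scores, plate correction, flags

Features become scores via the robust transform
$s = 1.35\,(F - \mathrm{median}(F_\mathrm{WT}))/\mathrm{iqr}(F_\mathrm{WT})$;
the factor $2\,\Phi^{-1}(0.75) \approx 1.349$ makes $s$ read as "standard
deviations from the WT median" for normal data while staying
outlier-robust. At least 10 WT replicate rows are required; zero-iqr
features are dropped with a warning. Scores are affine-invariant in each
raw feature, so unit changes cannot alter them, and Pearson correlations
between score columns equal those between the underlying corrected
features.

Plate bias is corrected by forcing each plate's per-feature median to the
parental median — multiplicatively for strictly positive features, by shift
for sign-carrying ones (`rho_cd`); "set the median" is ambiguous between
shift and scale, and the multiplicative reading preserves positivity and
CV structure. A temporal correction for fraction-derived features
(`correct_time_bias()`: WT imaging-time trend removal by loess
median-recentring) is provided but off by default in `run_pipeline()` — the
generator injects no temporal drift, and the fuller regression-based
correction of the original analysis is under-specified at its source; this
recentring is the package's documented substitute and can be switched on
per run. Phenotypes are flagged at $|s| \ge 3$ by default (conservative,
~0.3 % false positives per feature under normality).

## Consensus islands

Strains with at least one flagged score, plus all WT replicates, are
embedded into 2D by t-SNE (`embed_tsne()`: exact-gradient implementation —
screens of this size need no tree approximation — with perplexity-calibrated
input affinities, early exaggeration, momentum gradient descent). Because
the embedding is stochastic, it is repeated `n_maps = 100` times with seeds
derived from the master seed (seed + map index), each map is clustered with
DBSCAN, and only *co-membership* is aggregated: $f_{ij}$ = fraction of maps
in which strains $i,j$ share a cluster. Pairs with $f_{ij} > 0.9$ are
linked and the connected components of size $\ge$ `min_points` are the
islands; everything else stays unassigned. The aggregation rule (pairwise
graph + components) is this package's formalisation of "clustering together
in more than 90 % of the maps", which the source states without an
aggregation rule.

Numerical choices:

* **Map rescaling.** Each map is rescaled to a common RMS radius
  (10 units) before clustering. The absolute scale of a stochastic
  embedding varies several-fold between runs (strongly so at small n), and
  a single DBSCAN ε is only meaningful across maps on a shared scale.
* **DBSCAN** (`dbscan_cluster()`) is the canonical density-reachability
  algorithm in an order-invariant formulation: clusters are connected
  components of core points, border points join their nearest core point.
  It is tested against a brute-force reachability oracle.
* **Perplexity** defaults to 30 (clamped to $(n-1)/3$); the planted-island
  validation is robust over perplexity 10–50.
* **ε tuning** (`tune_dbscan()`) maximises the island count subject to at
  least 90 % of WT replicates sharing one island. Ties in island count are
  resolved towards the radius with the highest WT bulk cohesion and then
  to the smaller radius: a too-small radius with the same island count
  merely strands borderline bulk strains as unassigned.
* **Stability** (`island_stability()`) re-embeds subsamples (50 disjoint
  ~2 % holdouts, 10 maps each by default; smaller settings are fine for
  small screens) and scores each reference island by the maximal fraction
  of its surviving members still clustering together — a Jaccard-style
  index, typically above 0.9 for real structure.

## Enrichment

Categorical enrichment (`term_enrichment()`) is a two-tailed hypergeometric
test, $p = \min(1,\, 2\min(P[X \le k], P[X \ge k]))$ — the doubling rule is
the package's two-tailed construction, capped at 1 — adjusted by
Benjamini-Hochberg for near-independent vocabularies (COG-style categories)
and Benjamini-Yekutieli where dependence is expected (GO-style terms).
Annotations are a flat id-term table; ontology-graph propagation is out of
scope.

Spatial enrichment (`safe_enrichment()`) treats an embedding as a map: the
neighbourhood of each point is the disc whose radius is the 1-percentile of
all pairwise distances, and each term's local count is tested against the
hypergeometric null given the neighbourhood size and the term's global
frequency, with BY adjustment across all point-term pairs at
$\alpha = 0.05$. A permutation background (mean, SD and empirical p of the
local count over `n_perm = 1000` attribute permutations) is reported
alongside: the original method mixes permutation language with a
hypergeometric test, so both routes are provided, with the analytic test
driving the significance calls. Type-I calibration under permuted
attributes is part of the acceptance suite.

## Feature network

Before network inference, `belsley_screen()` removes collinear features:
columns scaled to unit norm, SVD condition indices $\sigma_{max}/\sigma_i$,
and any feature with variance-decomposition proportion > 0.5 on an index
above 30 is excluded. The default network feature set is the screened
10-feature panel (`mean_length`, `mean_width`, `mean_area`,
`mean_nucleoid_area`, `alpha_max`, `od_max`, `rel_t_nuc`, `rel_t_const`,
`rho_cd`, `cdn_c0`).

`mutual_information()` rank-transforms both variables, bins into
$\lceil n^{1/3} \rceil$ equal-frequency bins and applies the Miller-Madow
correction; the estimator is validated against the Gaussian closed form
$-\tfrac12 \ln(1-\rho^2)$ to 0.03 nats at $n = 10^5$. The estimator is
pluggable (`n_bins`), since the original analysis delegates to an external
implementation without stating one.

`aracne()` applies the data-processing inequality: edge $(i,j)$ is removed
if some $k$ has $MI_{ij} < \min(MI_{ik}, MI_{jk})(1 - \text{tolerance})$,
always evaluated against the input matrix, so the result is
order-independent and idempotent; exact ties are kept (conservative).
On tree-structured dependence this recovers the tree exactly, which the
acceptance suite checks on Gaussian trees. `bootstrap_network()` resamples
strains with replacement 200 times and keeps edges present in more than
70 % of replicate networks. Within each replicate, edges below an MI
significance floor are dropped first; because bootstrap resampling
duplicates rows and thereby inflates binned MI above the iid chi-square
null, that floor is calibrated by permutation on bootstrap-resampled
independent pairs rather than taken from `mi_null_threshold()`. The result
is an undirected relevance network; no edge orientation is attempted.

## Confidence intervals, contours, densities

`fisher_pearson_ci()` is the Fisher-z interval
($z = \operatorname{atanh}\rho$, SE $1/\sqrt{n-3}$); it reproduces the
reference endpoints ±0.63 at $n=10$, ±0.06 at $n=1000$, and [0.83, 0.85]
for $\rho = 0.84$ at $n = 4227$, and holds 95 % ± 2 % coverage in
simulation. `kendall_bootstrap_ci()` is the 2.5/97.5 percentile interval
over 5000 resamples (Kendall's τ has no usable z-transform).
`kde_contours()` computes iso-density probability contours (0.5 / 0.75 /
0.95 by default) on a 128 × 128 lattice; the bandwidth is the
normal-reference rule, which satisfies the calibration requirement that
the 0.95 contour encloses 95 % ± 1 % of points — any selector meeting that
property is acceptable, and the choice is deliberately simple.
`local_density()` counts neighbours within the 0.03 percentile of pairwise
distances, read literally as quantile 0.0003; if the intended reading was
the 3rd percentile, pass `radius_percentile = 3`.

## Orchestration and reproducibility

`run_pipeline()` executes growth fits → features → plate (and optional
time) correction → scores → flags → consensus islands (skipped below 20
strains, where repeated-embedding consensus is not meaningful) → optional
enrichment → network, writing CSV outputs and a JSON manifest carrying the
config hash and seed. A single master seed fans out to per-stage and
per-map seeds by fixed arithmetic, so every output is a pure function of
(inputs, config, seed); reruns are byte-identical. The exported functions
are the interface; `scripts/acceptance.R` reruns the validation battery
end to end.

Problem sizes used by the test and acceptance battery — synthetic screens
of 40 WT replicates + 10 null mutants + 3 planted islands of 10 strains,
100 embedding maps, $10^5$-cell populations for distributional checks, 100
noisy growth curves, 1000 Fisher-coverage simulations — are the package's
validation choices: large enough for the stated tolerances, small enough to
run routinely.

## Known limitations

* Everything cell-cycle assumes steady-state balanced growth.
* The curation classifier is only as good as its training labels; on real
  screens those come from visual scoring, here from stylised corruptions.
* Consensus islands on fewer than ~50 strains are unstable because t-SNE
  neighbourhoods then span a large fraction of the data.
* The temporal-bias recentring is a deliberately simple stand-in for a
  fuller covariate model and defaults to off.
* Island counts and identities on real data depend on ε/minPoints and on
  the stochastic maps; the package validates recovery of planted structure,
  not any particular published island count.
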