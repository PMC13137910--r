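---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`noremod` implements a multi-omic analysis of nitric oxide (NO)-dependent
remodeling in classically activated macrophages. The biological design it
targets is factorial: genotype (wild-type vs iNOS knockout, i.e. with or
without endogenous NO production upon stimulation), LPS/IFN&gamma;
stimulation, and treatment with the slow-release NO donor DETA-NONOate,
whose role is to *rescue* NO-dependent effects in knockout cells. The
package covers the computational arm of such a study end to end:
preprocessing of protein intensity and RNA count matrices, differential
statistics, PCA-based contributor selection, a z-score classifier of NO
dependence, cross-model/cross-omic concordance, and gene-set
over-representation — all exercised on synthetic data with planted ground
truth, so every stage is testable without access to instrument data.

# The synthetic-data generator

The generator (`sim_params()`, `generate_proteomics()`,
`generate_counts()`) is a first-class module, not a test fixture: its
defaults define the study conditions under which the pipeline is validated.

**Latent proteome model.** Each feature has a baseline log2 abundance drawn
from Normal(20, 2), roughly the dynamic range of label-free protein
quantification. Condition effects are added on the log2 scale and the
matrix is exponentiated, so measurement noise (Normal, sd 0.25 log2 units
by default, about 19% CV) is multiplicative on the linear scale, as in real
intensity data.

**Planted classes.** Features belong to one of four regulatory classes:

* `NO_dep_up` / `NO_dep_down` respond whenever NO is present. "NO present"
  means (wild-type AND stimulated) OR donor-treated — the rescue logic: a
  knockout cell under DETA-NONOate behaves like a stimulated wild-type cell
  for these features.
* `NO_independent` features respond to stimulation in both genotypes.
* `null` features carry no condition effect; their true fold changes are
  exactly zero.

Absolute effect sizes are |Normal(1.5, 0.4)| log2 units.
`NO_independent` effects are additionally scaled by `stim_effect_scale`
(default 3), and the default class proportions are 0.1/0.1/0.3/0.5. Both
choices encode the same observation about classically activated
macrophages: general stimulation-induced remodeling involves far more of
the proteome, and larger shifts, than the NO-specific arm modulates.
Because the PCA stage scales every feature to unit variance, the dominance
of a principal axis is determined by *how many* features are correlated
along it rather than by their effect sizes; with fewer stimulation-driven
than NO-driven features the first principal component would become the NO
axis, inverting the structure the generator is meant to emulate
(stimulation on PC1, NO dependence on PC2). The sparser configuration with
10% NO-independent features and a 70% null background remains fully
supported and is exercised by the test suite; classifier recovery holds in
both regimes.

**Missingness.** Intensity missingness is left-censored: a cell with latent
log2 value $x$ is missing with probability
$\text{missing\_rate} \cdot \Phi(\text{censor\_strength} \cdot (\mu_{low} - x))$,
with $\mu_{low}$ the 10% quantile of latent values. Defaults
(rate 0.25, strength 1.0) concentrate missingness in low-abundance
features, which is the premise of down-shifted imputation. The TMT-like
path of the demo pipeline sets the rate to 0, since reporter-ion matrices
filtered to complete channels have no missing cells.

**RNA coupling.** True RNA effects are built from true protein effects as
$e_{rna} = \rho\, e_{prot} + \sqrt{1-\rho^2}\, s\, \varepsilon$ with $s$
the empirical sd of protein effects, so the correlation between true
effects across planted features equals `rna_protein_coupling` (default
0.6, in the range of published protein-transcript agreement for this
system). Counts are negative binomial with gene-level log-normal relative
abundances, uniform per-sample library sizes, and dispersion
`nb_dispersion` (default 0.05); dispersion near zero recovers Poisson
moments, which the tests verify.

**What the generator does not emulate.** Peptide-level quantification,
ratio compression, batch effects, per-sample loading differences,
transcript-length bias, and count outliers. Passing tests therefore show
that the *statistical machinery* behaves as specified under a clean
factorial model — not that the pipeline is robust to every artifact of
real acquisitions.

# Preprocessing

* `channel_normalize()` rescales each complete sample column to a total of
  100, the relative-percentage convention for TMT reporter intensities. It
  is idempotent and scale-invariant. A caveat documented here because it is
  easy to miss: sum normalization is compositional. When regulation is
  unbalanced (more total signal gained than lost in a condition), forcing
  equal column totals pushes all unregulated features in the opposite
  direction, which downstream looks like coherent regulation of null
  features. On real reporter data only relative signal is meaningful and
  the step is unavoidable; on the simulated demo data, which are generated
  loading-balanced on an absolute scale, the step would only inject that
  artifact, so the demo pipeline leaves it off (`pipeline_config(channel_normalize = )`).
* `filter_complete()` implements the two published retention rules: rows
  with all samples observed (complete TMT matrices) or rows with at least
  `min_valid` observed values (default 16, against the 32-sample design).
  The boundary is inclusive: exactly 16 observed values is retained.
* `impute_downshifted()` replaces missing cells, separately per sample
  column, with draws from Normal($\mu_j - 1.8\sigma_j$, $(0.3\sigma_j)^2$)
  where $\mu_j, \sigma_j$ are the observed column mean and sd — the
  down-shifted narrowed Gaussian convention for left-censored proteomics
  missingness. Columns with fewer than 3 observed values are an error
  rather than a silent guess. The (n−1) sample sd is used here and
  everywhere else in the package.
* `row_zscore()` centers and scales rows to mean 0, sd 1, dropping
  constant rows. Z-scores are *analyzed* uncapped; the ±2 cap used for
  heatmap display (`plot_zscore_heatmap()`) is applied at rendering only.
* Log2 and back-transforms are explicit operations with a tracked
  `scale_state`, because the published workflow tests on linear-scale
  values while imputing and z-scoring on the log2 scale; the state machine
  makes order-of-operations bugs loud.

# Differential statistics

**Intensities.** Per-feature two-sided Welch (unequal-variance) t-tests on
linear-scale intensities, fold changes as log2(mean contrast / mean ref),
Benjamini-Hochberg adjustment across features. Testing on the linear scale
follows the published convention; it is mildly heavy-tailed for log-normal
noise, and the null simulations show slightly conservative behavior
(~3.5–4% rejection at nominal 5% with n = 4 per group). A log-scale option
is deliberately not the default.

**Counts.** `nb_wald()` is a transparent simplification of the NB-GLM
framework: median-of-ratios size factors; method-of-moments gene
dispersions from within-group residuals (corrected for the variance
introduced by size-factor division), shrunk 50/50 toward a parametric
trend $\alpha(\mu) = a_0 + a_1/\mu$; two-group means on the normalized
scale; Wald statistic = lfc / delta-method SE with a standard-normal
two-sided p. It omits Cox-Reid adjusted-profile dispersions, fold-change
shrinkage and outlier refitting. Validation is therefore by parameter
recovery (planted log2fc = 1 recovered to within ±0.02 at n = 8/group) and
null calibration (5.5–7.5% rejection at nominal 5%), not by replication of
any published DEG catalogue. Genes with a zero group mean report a
sign-correct fold change capped at ±10 with `lfc_capped = TRUE`; inside the
SE only, group means are floored at half a normalized count.

Numerical notes: dispersions are floored at 1e-8; underflowing p-values
are floored at the smallest positive double so BH input stays in (0, 1];
size factors are defined only up to a global scale, so only their ratios
are meaningful.

# Structure: PCA, contributors, clustering, classification

`run_pca()` treats samples as observations, removes zero-variance
features, centers and scales each feature to unit variance, and computes
components by SVD. Variance explained is $100\,\sigma_i^2 / \sum_j \sigma_j^2$.
Because a principal axis has arbitrary sign, each component is oriented so
its largest-|loading| feature is positive — this makes "positive/negative
contributor" labels reproducible across platforms and BLAS libraries.

`select_contributors()` flags features whose loading on a chosen component
(PC2 by default in the pipeline, the NO axis) lies beyond the mean ± 2 sd
of that component's loadings. Note that planted or real outliers inflate
the loading sd themselves, so with many moderate loadings a few background
features near the band edge are expected alongside true outliers.

`cluster_rows()` clusters features on Pearson correlation distance
(1 − r) with Ward.D2 linkage. Ward linkage on a non-Euclidean distance is
a heuristic, used here because it is the convention of the heatmap
software this stage mirrors; the merge sequence is validated against a
naive agglomeration oracle. Dendrograms export to Newick via `ape`.

`classify_no_dependence()` computes, per feature of a row-z-scored matrix,
condition means over the four donor-free genotype × stimulation cells and
the three effect statistics (wild-type stimulation effect, knockout
stimulation effect, and their difference, the NO effect), then applies the
four threshold rules (0.4 on stimulation effects, 0.5 on the NO effect, in
z units). The rules are mutually exclusive and exhaustive for any real
triple, which the suite fuzz-tests. Two open choices were resolved as
follows, both exposed as arguments:

* Condition means are taken over replicate z-scores (not z-scores of
  replicate means), because the replicate-level matrix is what the
  clustering stage consumes.
* The demo pipeline classifies only features significant (BH p < 0.05) in
  the NO contrast or the wild-type stimulation contrast
  (`classify_significant_only`). Row z-scoring amplifies pure noise to unit
  variance, so on an unfiltered matrix a null feature crosses the
  fixed z thresholds with ~15% probability per direction at n = 4 — the
  significance gate removes that false-positive mass and is, in effect,
  what an analyst does by classifying a heatmap of responsive proteins.
  Set the flag to `FALSE` to classify every feature.
* Donor-rescue comparisons reuse the same operation with a remapped design
  in which the donor axis plays the stimulation role.

# Concordance

Gene matching is a case-insensitive inner join on symbols (tables must be
isoform-collapsed first). The five agreement categories follow
significance in each dataset at BH p < &alpha; (default 0.05) and
fold-change sign agreement; a fold change of exactly 0 in a significant
pair is counted as concordant with the other dataset's sign (a measure-zero
tie-break that can occur with capped fold changes). Strong responders
additionally require |log2FC| > 0.5 in both datasets and are ranked within
quadrant by the sum of absolute fold changes. Triple concordance keeps
genes significantly *down* in both proteomes and the transcriptome (the
highest-confidence NO-induced genes, since the contrast is knockout over
wild-type), ranks them by the designated dataset's fold change (most
negative first, ties by symbol), and flags NO-inducible genes — those also
significantly up under stimulation in wild-type cells.

# Enrichment

`enrich()` is a local replacement for web-service over-representation:
exact upper-tail hypergeometric p per set, BH across the sets of one
library, filtering at adjusted p < 0.05. The universe is explicit — by
default in the pipeline, all quantified genes intersected with the union
of library members — because the per-library backgrounds of web services
are not reproducible locally; this is the main expected numerical
divergence from any web-service output. Sets are trimmed to the universe
before testing (conditional-on-measured convention); matching is
case-insensitive. A curated library ships in
`inst/extdata/curated_no_gene_sets.gmt`: electron-transport-chain
complexes I–V, COX assembly chaperones (kept separate from complex IV
structural subunits), mitochondrially encoded genes, and a denitrosylase
list.

# Pipeline, provenance and problem sizes

`run_pipeline()` executes simulate → preprocess → differential →
structure → concordance → enrichment, writing one TSV per stage stamped
with a hash of the full configuration, a JSONL log line per stage, and a
run-metadata JSON. `pipeline_report()` assembles a plain-text summary and
refuses directories whose outputs carry mixed config hashes. The demo
enrichment stage uses a synthetic library derived from the planted truth
(set names prefixed `SYNTH_`) unless a GMT path is configured.

Default problem sizes — 2,000 features, the 32-sample and 16-sample
proteome designs, 12 RNA samples, 5-seed replication for recovery
statistics, 10^5-triple fuzzing, exhaustive hypergeometric checks to
universe size 60 — keep a full validation run around half a minute while
leaving all recovery and calibration margins wide; they are choices of the
package, and all scale up through `sim_params()`.

# Known limitations

* The NB stage is intentionally simpler than full NB-GLM frameworks; with
  very few replicates or strong outliers its Wald p-values are less robust
  than Cox-Reid/shrinkage-based ones (null rejection runs ~1–2 points
  above nominal at n = 4 per group).
* Welch tests on linear intensities inherit the heavy tails of linear
  abundance data.
* Sum (relative-percentage) normalization is compositional; see above.
* The fixed z-score thresholds (0.4/0.5) are inherited conventions, not
  estimated quantities; their false-positive behavior without the
  significance gate is documented above.
* Enrichment results depend on the chosen universe; no attempt is made to
  reproduce web-service backgrounds.
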