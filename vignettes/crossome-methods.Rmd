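---
title: "Cross-ome fingerprinting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ome fingerprinting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossome)
```

`crossome` analyses a genotype panel measured on two omic layers — a
protein abundance matrix and a lipid abundance matrix over the same
samples, both on log2 scale — and extracts "molecular fingerprints":
groups of lipids and proteins that co-vary across the genotypes, the
annotation terms those groups are enriched for, and per-genotype summaries
of how strongly each fingerprint is perturbed. This vignette explains the
underlying model, the tunable parameters and why their defaults are what
they are, what the synthetic data generator does and does not emulate, and
the numerical corner cases.

## The measurement model and its assumptions

The pipeline assumes that each layer is a features-by-samples table of
log2 intensities with missing values, that the two layers share the same
samples, and that samples are organised as a control genotype plus mutant
genotypes with a few replicates each. It does **not** assume the two
layers share an intensity scale, a noise model, or a missingness rate —
which is exactly why the association statistic is a rank correlation.

The scientific premise is simple: when a mutation perturbs a pathway, the
proteins and lipids downstream of that pathway shift together in the
affected genotypes. Across a panel of many genotypes, such co-perturbed
features produce concordant abundance rankings, and Kendall's tau-b
captures that concordance robustly:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}, \qquad
n_0 = \tfrac{n(n-1)}{2}$$

with $C$/$D$ the concordant and discordant pair counts and $n_1$, $n_2$
the tie corrections for each argument. Pairs with a missing value in
either profile are dropped (pairwise-complete); a cell is reported missing
when fewer than `min_overlap` usable pairs remain or either profile is
constant over them.

## Stage-by-stage parameters

### Detection filter and fold changes

* `detection_filter(min_fraction = 0.5)` — features quantified in fewer
  than half the samples are removed before correlation. Rank correlations
  on pairwise-complete data degrade badly once most pairs are imputed away;
  50% is a conservative, conventional floor.
* `median_center()` — optional per-sample median subtraction (off by
  default in `run_config()`). Whether upstream quantification already
  normalised sample loading varies between pipelines, so centering is a
  flag rather than an assumption. Centered or not, a location shift common
  to all samples cancels in every downstream statistic.
* `log2fc_vs_control(min_reps = 2)` — a genotype's fold change for a
  feature is the mean over its non-missing replicate log2 values minus the
  control mean, reported only when both sides have at least `min_reps`
  replicates (of typically four). Requiring two tolerates a single dropout
  without ever reporting a single-replicate "mean". No imputation is
  performed anywhere: imputation would fabricate exactly the correlation
  structure the pipeline is designed to detect.

### Correlation and connectivity filter

* `profile_mode` — `replicate_level` (default) correlates across all
  samples; `genotype_mean` first collapses each feature to per-genotype
  means. Replicate-level profiles use all of the information in the panel
  and are the less lossy choice; genotype means suppress replicate noise
  at the cost of far fewer points per correlation. Both are one flag
  apart, and with a quadruplicate panel of a dozen-plus genotypes both
  modes clear the same `min_overlap`.
* `min_overlap = 12` — below roughly a dozen usable pairs, tau-b is so
  quantised that a fixed threshold like 0.4 stops being meaningful
  (with n = 6 complete pairs, adjacent achievable tau values are ~0.13
  apart), so sparser cells are reported missing rather than unstable.
* `filter_connected(tau_threshold = 0.4, min_partners = 2)` — a feature is
  retained only with at least two partners at |tau| **strictly** above
  0.4. The comparison is strict and the partner count is taken in a single
  pass against the full pre-filter matrix: iterative re-pruning after
  removals would make the retained set depend on removal order and is not
  what a one-shot connectivity criterion means. Missing cells never count
  as partners — absence of evidence is not a partner.

### Clustering

* The dense tau matrix (missing cells set to 0, the null-association
  value, for distance computation only) is clustered twice per axis:
  hierarchical clustering with average linkage on Euclidean distances
  supplies the heatmap ordering, and k-means supplies the discrete
  assignments. Average linkage is the common heatmap default; the choice
  is echoed into the run provenance rather than hidden.
* k-means uses k-means++ seeding, `restarts = 50` independent starts, and
  keeps the lowest within-cluster sum of squares. Features are put into a
  canonical sorted order before seeding, so assignments cannot depend on
  input row order; a fixed `seed` makes them bit-reproducible. Lloyd
  iterations only ever decrease the objective, and equidistant points
  resolve to the first matching centroid, so ties cannot oscillate.
* Default `k`: 18 on the protein axis and 13 on the lipid axis — sensible
  for a panel-scale fingerprint matrix with a few hundred retained
  features per axis; 14 lipid clusters is an equally defensible
  convention for the same data and is one flag away (`k_lipid = 14`).
  There is no automatic k selection; k is a reporting resolution here,
  not an estimand.

### Enrichment

* `fisher_enrich()` is one-sided (upper tail): the question asked of a
  cluster is always "is this term over-represented", and depletion is not
  used downstream. The p-value is the exact hypergeometric tail
  $\sum_{k \ge a} \binom{K}{k}\binom{N-K}{n-k}/\binom{N}{n}$.
* The background is the set of features that survived the connectivity
  filter on that axis — the tests condition on a feature having entered
  the analysis at all, which is the comparison a cluster membership
  question implies. A custom background can be supplied.
* BH q-values are computed over all (cluster, term) pairs of one layer's
  run, matching the matrix-wide readout of a clustered heatmap.
* `class_rank_test()` asks whether a lipid class skews toward the top of a
  genotype's fold-change ranking. Ranks are averaged over ties; the exact
  Wilcoxon rank-sum null is used when min(group sizes) ≤ 10, N ≤ 30 and
  there are no ties, otherwise a normal approximation with tie-corrected
  variance and continuity correction. The switch is deliberately
  conservative and unit-tested on both sides of the boundary.

### Signatures, networks, outliers

* Cluster signatures default to **sums** of member log2 fold changes (a
  cluster-level total burden), curated-set signatures to **means** (an
  average module abundance); both are explicit `mode` arguments and are
  recorded in the output.
* `extract_network()` keeps correlations touching a seed feature with
  |tau| strictly above the threshold; raising the threshold always yields
  a subgraph. Category labels for `top_partner_frequency()` are
  user-supplied maps, not hard-coded gene lists — which proteins count as
  "autophagy receptors" is biological curation, not computation.
* `outlier_analysis()` uses a robust z per feature across genotypes,
  $(x - \mathrm{median})/(1.4826\,\mathrm{MAD} + \varepsilon)$ with
  $\varepsilon = 10^{-9}$ and a standard-deviation fallback when the MAD
  is 0 (so an all-equal feature flags nothing), cutoff 2.5, and at least
  10 genotype values per tested feature. A z-score on fold changes is one
  reasonable operationalisation of "this genotype behaves differently for
  this molecule"; rank- or model-based criteria are plausible
  alternatives, which is why the cutoff and the statistic's inputs are
  config-exposed rather than baked in.

## The lipid shorthand parser

Lipid names arrive as shorthand: `CLASS[qualifier] [prefix-]C:D[_C:D...]`.
The parser accepts both `_` and `/` chain separators (sn-position is
ignored — nothing downstream uses it), `O-`/`P-` ether prefixes
(plasmanyl/plasmenyl), `d`/`t` sphingoid prefixes, and bracket qualifiers
as part of the class (`Cer[NS]`). A single `C:D` token is a sum
composition (`resolution = "species"`); enumerated chains sum to the
totals (`"molecular"`). Headgroup tokens like `GM3` parse as the class,
since class-level enrichment is the only consumer. Hydroxyl/oxygen
suffixes beyond `d`/`t` are not interpreted. Unknown grammars either error
(strict mode) or degrade to an `"unclassified"` term, so a panel with a
few exotic names never stalls the pipeline.

## What the generator emulates — and what it does not

`simulate_panel()` draws per-feature baselines from N(20, 3) log2 units,
adds `effect_size = 1.5` to module members in each module's affected
genotypes (3 of 12 mutants by default), adds N(0, 0.4²) replicate noise,
and applies 5% random dropout plus an intensity-dependent (MNAR)
component: cells below the panel's 10th abundance percentile drop out with
probability $\mathrm{logit}^{-1}(\text{slope}\cdot(q_{10} - x))$,
slope 1.0. These defaults describe a realistic quadruplicate MS panel: a
1.5 log2-unit effect is a strong but common knockout phenotype, 0.4 log2
units is a typical replicate CV for label-free quantification, and MS
dropout is well known to concentrate at low intensity.

Two generator choices matter for interpretation:

* Effects are planted on genotype means, not on correlations directly —
  cross-ome tau arises only through the shared affected-genotype pattern,
  so a recovery test exercises the entire chain (fold changes,
  correlation, filtering, clustering, enrichment) rather than any stage
  in isolation.
* Each module's affected-genotype triple is drawn distinct from the other
  modules' triples. Two modules perturbed in identical genotype subsets
  would be statistically indistinguishable by construction, and a
  benchmark should not punish an algorithm for a non-identifiable truth.

The generator does **not** emulate instrument drift across acquisition
batches, correlated noise between features, realistic lipid co-regulation
beyond the planted blocks, or annotation terms that partially overlap
modules. Passing recovery tests therefore demonstrates that the machinery
is correct and well-calibrated on clean planted structure — not that real
panels will yield clusters this clean.

## Problem sizes and evaluation choices

The recovery benchmark runs the full pipeline on the default panel
(12 mutants + control × 4 replicates, 600 proteins, 300 lipids, 5 modules)
over 10 seeds, clustering with k equal to the number of planted modules —
the resolution at which an adjusted Rand index against the planted labels
is meaningful. The connectivity filter itself performs the relevant model
selection: essentially only module members survive it, since unperturbed
features have no genotype-driven correlation structure. Unit tests use
smaller panels (tens of features, 3–8 genotypes) chosen to keep each
property readable and quick while still covering every code path;
oracle comparisons (exhaustive tau-b enumeration, hypergeometric tail
summation, rank-placement enumeration) run at sizes where exhaustion is
exact.

## Degenerate inputs and numerical notes

* Constant profiles and fewer than two complete pairs give a missing tau,
  never 0/0.
* A sample with no quantified values cannot be median-centered and is an
  error naming the sample; a feature with no control quantification warns
  and yields an all-missing fold-change row.
* An empty connectivity-filter result is valid (warning, empty matrix);
  an empty extracted network is valid.
* `bh_adjust()` rejects p-values outside (0, 1] rather than silently
  clamping.
* All seeded stages save and restore the caller's RNG state, so a
  pipeline run never perturbs surrounding code's random streams; reruns
  with the same configuration are byte-identical on the TSV outputs.

## Known limitations

* Partner counting, clustering, and enrichment all condition on the
  connectivity filter; features whose association is real but spread over
  a single strong partner are dropped by design (two-partner rule).
* No p-values are attached to individual tau values or network edges —
  the filter is a connectivity criterion, not a significance test.
* No batch correction across acquisition sets is included; if batches are
  confounded with genotypes, correlations will reflect that.
* The lipid parser covers shorthand nomenclature, not systematic names,
  masses, or isomer disambiguation.
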