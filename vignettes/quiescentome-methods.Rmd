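---
title: "quiescentome: models, parameters and design choices"
author: "quiescentome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quiescentome: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, every tunable parameter with
its default and rationale, the numerical edge cases, and — importantly —
what the synthetic benchmarks do and do not demonstrate about real data.

## The study design being modelled

The pipeline targets a paired 2×2 bulk-transcriptome design: macrophages
differentiated from cord-blood monocytes with or without human lactoferrin
(conditions `hlf` and `uM`), each subsequently stimulated with LPS or left
untreated (`hlf_LPS`, `uM_LPS`), with the *same four donors* contributing
one sample to every condition. Four condition contrasts are analysed:
`hlf_vs_uM`, `uM_LPS_vs_uM`, `hlf_LPS_vs_uM_LPS`, and `hlf_LPS_vs_hlf`.
The biological signature of interest is that the last contrast is empty —
lactoferrin-differentiated macrophages barely respond to LPS — and the
synthetic generator plants exactly that structure.

## Differential expression

### Linear model

`fitLinearModel()` fits ordinary least squares per gene with a shared
design matrix `~ 0 + condition + donor`. Donor blocking is the default
because the design is paired; a `donorBlocking = FALSE` switch drops the
donor terms for unpaired data. The residual degrees of freedom with four
donors and four conditions are `16 − 7 = 9`. Rank deficiency (e.g. donors
nested in conditions) is an error that names the collinear columns rather
than silently dropping them.

### Empirical-Bayes moderation

`eBayesModerate()` places the standard scaled inverse chi-square prior on
gene variances and estimates its hyperparameters by closed-form moment
matching on the log scale. With `e_g = log s²_g − ψ(d/2) + log(d/2)`:

* `E[e] = log s₀² + ψ(d₀/2) − log(d₀/2)`
* `Var[e] = ψ′(d/2) + ψ′(d₀/2)`

so `d₀` follows from a Newton inversion of the trigamma function and `s₀²`
from the mean. A closed-form estimator was chosen over iterative maximum
likelihood because it is deterministic, fast, and testable against an
independent reference implementation (the test suite checks agreement with
`limma::eBayes` to near machine precision on variance-heterogeneous data).

Edge cases: when the log-variance dispersion does not exceed its sampling
noise, the prior is effectively infinitely informative (`d₀ = ∞`) and every
posterior variance equals the pooled mean variance. Exact-zero residual
variances are floored at `min positive s² × 1e−8` with a warning before
taking logs; if *all* variances are zero the function falls back to
ordinary t-statistics with a warning. Moderated p-values use `d + d₀`
degrees of freedom.

### Selection cutoffs

`selectDEG()` defaults to FDR < 0.05 and |log₂FC| > 0.58 with **strict**
inequalities on both, a literal reading of "below −0.58 and above 0.58";
both thresholds are arguments, and `lfcCut = 0` reproduces the sensitivity
mode in which only the FDR rule applies. `adjustBH()` is the textbook
step-up (sort, scale by `n/rank`, cumulative minimum from the largest
p-value, cap at 1), verified against a brute-force implementation and
`stats::p.adjust` on a thousand random vectors.

### Targeted ANOVA

`anovaTukey()` wraps `stats::aov` and `stats::TukeyHSD` per gene for the
targeted cytokine comparisons; these are standard procedures and are
deliberately not re-implemented.

## Enrichment

`matchedBackground()` operationalizes "genes with similar expression" as
**equal-frequency bins of mean expression** (default 10 bins, ties broken
by gene order for determinism): the background is the union of all bins
occupied by at least one test gene, so it is always a superset of the test
set. Ten bins keeps ~200 genes per bin at the default universe size —
coarse enough to be stable, fine enough to matter; the count is an
argument.

`oraHypergeometric()` tests `P(X ≥ k)` for overlap `k` between `n` test
genes and the `K` set members inside the `N`-gene background. ORA rather
than a ranked statistic is the deliberate choice because the surrounding
workflow defines *threshold* inputs (FDR < 0.1 genes for the main
enrichment, strict DEG for the theme comparison); sets with no background
member are dropped rather than reported at p = 1.

`themeCompare()` joins per-contrast enrichment over the union of sets with
adjusted p < 0.1 in at least one contrast; every set in the union is
reported for every contrast with a significance flag, so opposed
regulation is visible rather than censored. The direction tag is the sign
of the mean log₂FC of a set's member DEG; an exactly zero mean (or no
member DEG) yields `"mixed"`.

`degPathwayAdjacency()` applies the strict |log₂FC| > 2.5 visualization
filter and emits both the 0/1 membership matrix and a chord-ready edge
list. An empty result is valid output, not an error.

## Regulator networks

`buildCoexpressionNetwork()` computes pairwise unsigned Pearson
correlations, raises them to the smallest integer power β in 1..20 whose
weighted-degree distribution reaches scale-free fit R² ≥ 0.85
(`scaleFreeFit()`: R² of `log10 frequency` on `log10 degree` over ten
equal-width bins), and retains exactly `ceiling(0.05 × candidates)` edges
network-wide. If no power reaches the target R², the best-fitting power is
used with a warning — synthetic data with only a planted module often has
no truly scale-free topology, and failing hard would be wrong. Ties in
edge weight are broken by gene symbols so outputs are deterministic. No
topological-overlap transform is applied (it is not part of the modelled
procedure). The "top 5%" rule is applied network-wide *before* restricting
to regulator-incident edges.

`regulatorEnrichment()` uses one-sided `stats::fisher.test` per regulator
(enrichment direction only), Benjamini–Hochberg adjustment across
regulators, and a Storey-type q-value (π₀ estimated as `2 × mean(p >
0.5)`, capped at 1). Significance requires adjusted p < 0.05 *and*
q < 0.2. Empty target sets score p = 1 and are flagged, not dropped.

`regenrichScore()` defines the composite regulator importance as the sum
of two components, each the rank-normalized `−log₁₀ p` (average ranks on
ties, scaled to [0, 1]) of (i) the regulator's own differential p and (ii)
its target-set enrichment p. The reference method's score formula is not
published in the modelled procedure, so this package defines its own:
rank-normalization makes the score invariant to monotone transformations
of either p-vector, bounded in [0, 2], and monotone in both evidence
sources — the three properties the tests assert. Zero p-values are clamped
to the machine minimum with a warning. Top-k extraction (k = 25 for the
expression heatmap, k = 20 for the score bar chart, k = 5 per pathway for
the Sankey attribution) breaks ties by component score, then gene symbol.

## Interaction propensity

Macrophage expression enters as **condition means across donors** (the
model scores conditions, not samples), standardized per gene across the
four conditions; partner-cell profiles are standardized per gene across
cell types. Standardization uses the sample standard deviation (n − 1) by
default — `populationSd = TRUE` switches to the n denominator — and
zero-variance genes become all-zero rows with a warning. Standardizing
each matrix over its own columns is what makes the edge products
comparable "arbitrary units" across cell types and conditions.

`interactionPropensity()` sums, over the edges of one channel, the product
of the two partners' z-scores. The soluble channel is macrophage-outgoing
only (the cytokine sits on the macrophage side of each directed edge);
physical edges are undirected and are summed over **both orientations**
(each side may be expressed by either cell). Edges whose genes are missing
from a matrix are *skipped, never imputed as zero*, and tallied in a
coverage report whose used + skipped counts always equal the channel's
edge total — silent partial coverage would make scores incomparable
between runs. `relativeToReference()` subtracts the untreated reference
condition per cell type and channel. `interactionDrivers()` decomposes a
between-condition propensity difference into per-gene contributions that
sum *exactly* to the total (the tests require 1e−9), with
`interaction_count` the number of distinct partner cell types reached
through at least one covered edge with nonzero partner expression.

## The synthetic-data generator

`simulateExpression()` draws

```
y[g, s] = baseline[g] + donorEffect[g, donor(s)] + effect[g, cond(s)]
          + moduleSd · w[module(g), s] + ε[g, s]
```

with `baseline ~ U(4, 12)` log₂ units, `donorEffect ~ N(0, 0.5)` shared
across a donor's four conditions (this is what makes donor blocking
meaningful), `ε ~ N(0, 0.2)`, and planted condition effects of magnitude
`U(1, 3)` with random sign: 4% of genes carry a lactoferrin effect applied
*identically* to `hlf` and `hlf_LPS`, and a disjoint 6% carry an LPS
effect in `uM_LPS`. The `hlf_LPS_vs_hlf` contrast is therefore an exact
null, and the `hlf_LPS_vs_uM_LPS` contrast is differentially expressed for
the union of both planted sets — the structural signature of
LPS-unresponsiveness after lactoferrin differentiation.

The per-module latent factor (`moduleSize = 50` genes, `moduleSd = 0.35`,
i.e. within-module correlation ≈ 0.5 against donor-plus-residual noise)
deserves its own justification. Real transcriptomes are strongly
co-expressed — the network stage's whole premise — and multiple-testing
behaviour differs between independent and positively dependent genes:
under independence the probability of at least one false BH discovery in a
global null contrast is exactly the nominal 5% (Simes), whereas under the
positive dependence that co-expression induces, step-up FDR control is
conservative and a null contrast is clean in ≈98% of replicates. The
module structure therefore makes the generator's null behave like a real
array null, and gives the co-expression stage genuine structure to find.
Each gene's marginal distribution remains exactly normal, so per-gene
p-values stay exactly calibrated (verified by a Monte-Carlo test).

Annotations assign exact fractions of genes per class (defaults: 10%
cytokine, 15% membrane, 10% regulator, 15% innate), drawn independently so
classes overlap as real registries do. Gene sets (default 50, sizes
10–60) include planted sets drawing 80% of members from true DEG of a
chosen contrast. The interaction generator connects membrane genes
physically, draws soluble cytokine→receptor edges, and plants a
configurable number of soluble edges whose cytokines carry a positive
lactoferrin effect and whose receptors are expressed by exactly one target
cell type; after standardization, each planted edge contributes
`√3 · (m−1)/√m` to the hlf-vs-uM propensity delta for that cell type
(`m` = number of cell types), giving a closed-form expectation the tests
and the acceptance script check to within the noise tolerance.

What the generator does **not** emulate — and hence what passing
benchmarks cannot show: probe-level microarray artifacts, batch and
scan-date effects, heavy-tailed or intensity-dependent noise, realistic
pathway topologies or annotation biases, receptor-complex stoichiometry,
and absolute cytokine secretion. Recovery rates measured here are upper
bounds on what identically parameterized real data would give.

## Problem sizes and reproducibility

The test suite and acceptance script use 2000-gene, 16-sample experiments
for the end-to-end properties (20 replicates), 150–1000 genes for
calibration Monte-Carlos, and toy instances for the exact oracles; these
sizes were chosen so the full verification cycle runs in well under a
minute on a laptop while keeping every binomial tolerance meaningful. All
randomness is seeded: the default generator seed is 17, every output
directory carries a manifest with the seed and a config hash, and two runs
with equal hashes produce byte-identical files.

## Known limitations

* The composite regulator score is this package's own definition (see
  above); scores are comparable within a run, not across packages.
* Propensity scores are descriptive ("arbitrary units"); no significance
  model is attached to them, by design.
* The scale-free target R² ≥ 0.85 is rarely reached on small synthetic
  matrices; the fallback to the best-fitting power is logged and the
  chosen β is recorded in the network object.
* Probe-to-gene collapse, intensity filtering, and normalization beyond
  the quantile step are upstream of this pipeline's contract: inputs are
  assumed to be a normalized log₂ gene-level matrix.
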