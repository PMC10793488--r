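---
title: "Methods: quantifying neutrophil-like monocyte states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutrophil-like monocyte states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neumo)
library(dplyr)
```

`neumo` implements the computational procedures behind a line of work that
characterizes monocytic myeloid-derived suppressor cells (M-MDSC) as being
enriched for a *neutrophil-like monocyte* (NeuMo / Neu-like) transcriptional
state, and that quantifies how glucocorticoid (dexamethasone, DEX) exposure
reshapes both differential expression and state usage. This vignette is the
package's own account of the models, their assumptions, the tunable
parameters, and the numerical conventions — and of what the synthetic-data
generators do and do not establish about real data.

## 1. The paired differential-expression substrate

All downstream statistics consume per-gene pairs of (log2 fold change, FDR)
for an M-MDSC-vs-monocyte contrast, computed separately for
glucocorticoid-exposed ("Yes-DEX") and unexposed ("No-DEX") subjects.

- **Filtering.** `filter_low_expression()` keeps genes with CPM strictly
  above `cpm_min` (default 1) in strictly more than `min_samples` (default
  3) samples — i.e. at least 4 qualifying samples. CPM always uses the raw,
  unfiltered library sizes, which makes the filter idempotent and
  independent of which other genes are removed. The "more than 3" rule is
  read strictly; the boundary is covered by a test.
- **Transform.** `log2cpm()` computes `log2(count/library * 1e6 + c)` with
  pseudocount `c = 1` by default, on raw library sizes (no TMM or other
  normalization factors — none are assumed, and both choices are
  configurable). Because the upstream study does not state its prior count,
  absolute score magnitudes are not bit-reproducible across
  implementations; every statistic in this package that is asserted against
  an external number is therefore either count-based or computed from
  printed inputs.
- **Paired test.** `paired_de()` is deliberately simple: per-gene log2FC is
  the mean over subjects of the case-minus-control log2CPM difference, and
  the p-value is a two-sided paired t-test on those per-subject differences,
  BH-adjusted over all tested genes. This is a stand-in for count-model
  fits (e.g. quasi-likelihood negative-binomial GLMs): the downstream
  statistics consume only (log2FC, FDR), and `read_deg_table()` ingests any
  externally computed table (TSV/CSV/XLSX with a column mapping), so the
  attenuation and enrichment machinery is agnostic to how the DE table was
  produced. Degenerate genes with zero variance of differences get p = 1
  when the mean difference is also zero, and the smallest representable
  double — flagged in a `degenerate` column — when it is not; they are never
  silently significant.

The paired t stand-in holds its nominal type-I error on null simulations
(asserted at 0.05 ± 0.02 over 20 replicates of 2000 genes in the test
suite), which is all the downstream stages require of it.

## 2. The DEX-attenuation statistic and its resampling null

For a gene differentially expressed in the *same direction* in both arms,

$$ r = \frac{\text{log2FC}_{\text{Yes-DEX}}}{\text{log2FC}_{\text{No-DEX}}} $$

is positive; $0 < r < 1$ is *attenuation* (the drug shrank the difference),
$r > 1$ is *potentiation*. `classify_attenuation()` labels each gene
`attenuated`, `potentiated`, `neutral` (exactly 1 — the boundary is not
addressed in the source description, so strict inequalities are used and
exact ties get their own class), or `discordant` (opposite signs; the ratio
is undefined and the gene is excluded from counting). `ratio_of_log2fc()`
is scale-invariant under any sign-preserving rescaling of both arms.

Whether the observed number of attenuated genes among the shared DEGs is
surprising is judged by `attenuation_null()`: each of `n_iter` iterations
samples `n_draw` genes **without replacement** (with-replacement is an
option) from the universe of all same-direction analyzed genes — discordant
genes are excluded *before* sampling — and counts ratios strictly in (0, 1).
`attenuation_test()` reports the add-one empirical p,
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{iter}} + 1)$, which can
never be zero, plus an `outside_range` flag against the null min–max. The
defaults (`n_draw = 666`, `n_iter = 100000`) are the published study's
configuration; tests and the pipeline scale both down since the null mean
and range stabilize quickly.

The null is exactly hypergeometric in the number of attenuated genes, which
provides a closed-form oracle (mean `n_draw * K/N`) used in the tests; the
empirical p is verified to be uniform when the observed count is itself a
null draw, and on simulations with `attenuation_factor = 1` the observed
count falls inside the null range in at least 95% of replicates.

The *equivalent change index* for comparing a gene's fold changes across
studies is implemented as
$\mathrm{sign}(ab)\cdot\min(|a|,|b|)/\max(|a|,|b|)$ — bounded in [-1, 1],
symmetric, 1 for equal nonzero changes, negative for opposite directions, 0
when one change is zero. The published usage cites but does not define the
formula, so this definition was chosen for its interpretability and is
deliberately isolated in one function should a different convention be
needed.

## 3. Preranked enrichment and the consensus metagene

`enrichment_score()` is the classic weighted Kolmogorov–Smirnov running
statistic on a descending ranking (typically by log2FC): in-set genes add
$|s|^{w}$ normalized by the in-set total, out-of-set genes subtract
$1/(N - N_{hit})$; the ES is the running value of maximal absolute
deviation, and the leading edge is the in-set genes at or before the peak
(after, for negative ES). Ties in scores are broken lexicographically by
gene id so rankings are reproducible. The default exponent `weight = 1` is
the standard weighted statistic (0 and 2 are supported); the upstream
tool's exact settings are unreported, so NES magnitudes are treated as
non-reproducible and nothing external is asserted about them.

`preranked_gsea()` builds the null by permuting the gene labels of the
scores — for a preranked analysis this is equivalent to placing the set at
random positions, which is how it is implemented (a closed-form ES from hit
positions alone; an O(k log k) per-permutation path). NES divides ES by the
mean absolute null ES of matching sign; p-values are matching-sign tail
probabilities with the add-one convention; FDR follows the pooled-null-NES
procedure (pooled null proportion at least as extreme, normalized by the
observed proportion, capped at 1). The observed ES used for tail comparisons
is computed with the same arithmetic path as the null so that placements
with mathematically equal ES tie exactly. The implementation is verified
three ways: a hand-enumerated running sum, exhaustive enumeration of all
$\binom{N}{k}$ placements on 8-gene rankings, and an independent ES
implementation (fgsea) on random cases.

The consensus signature is built from enrichment results per exposure arm:
`select_enriched()` keeps sets at `NES >= 2.5` and `FDR <= 0.05` (inclusive,
matching the "≥" phrasing of the construction; exact-boundary sets are
flagged so a strict reading can be audited); `majority_leading_edge()`
returns genes present in at least half of the selected sets' leading edges
(membership count `>= n_sets/2`, so 3 of 6 and 5 of 10; a strict-majority
option exists); and `consensus_signature()` intersects the two arms'
majority sets. Provenance sufficient to regenerate the signature is stored
with it. `score_samples()` is the unweighted mean log2CPM over present
signature genes — missing genes are intersected with a warning by default
because external cohorts differ in symbol coverage. `expand_signature()`
adds genes with Pearson correlation at least 0.7 with the score, excluding
constant genes whose correlation is undefined.

`hypergeometric_ora()` provides generic over-representation p-values (upper
hypergeometric tail) for pathway analysis of signature genes; no pathway
knowledgebase ships with the package.

## 4. Guide-constrained NMF deconvolution

The two-state mixture model is $X \approx S F$ on **linear** CPM restricted
to marker genes — the additive mixing model is only meaningful on a linear
scale, so deconvolution never runs on log2CPM. `build_guide_matrix()` turns
a per-state log2 fold-enrichment table into a binary guide at cutoff 0.58
(about 1.5-fold, the published marker cutoff); genes passing for several
states are ambiguous and dropped with a warning (the published marker set
contains one-state markers only), genes passing for none are dropped
silently, and a state left without markers is an error.

`fit_semisupervised_nmf()` minimizes squared Frobenius error by
multiplicative updates. Signature entries at guide-zero positions are
initialized at zero and clamped to zero after every update, so the mask is
satisfied *exactly* (a projection, not a penalty); the multiplicative-update
monotonicity property is preserved and asserted (non-increasing loss traces
up to 1e-12 relative slack). Convergence is declared when the relative loss
change drops below `tol` (1e-6) or at `max_iter` (2000); `n_restarts`
(default 10) random nonnegative initializations are run from seeds derived
from the given seed, and the lowest-loss restart is kept.

**Identifiability.** $X = SF$ is invariant to a per-state rescaling
$S \mapsto SD^{-1}, F \mapsto DF$, so raw fractions are only defined up to
the scale convention of the signature matrix. Both the generator
(`simulate_mixtures()`) and the fitter adopt the standard convention of
normalizing signature columns to a common column sum before
simplex-normalizing the fraction columns; under that shared convention
fractions are identifiable, and noiseless recovery to within MAE 0.02 (and
RMSE 0.05 at 10% additive noise) is asserted across random guide-respecting
problems. On real data, reported fractions should be read as relative state
usage under the equal-signature-mass convention — as with any
signature-based deconvolution. Output fractions are exactly on the unit
simplex (within 1e-9) and invariant to an overall rescaling of the input.

## 5. Scores, group comparisons, and pooling across studies

`compare_scores()` uses the Wilcoxon rank-sum test for unpaired and the
signed-rank test for paired comparisons, reporting the raw mean difference
as the effect summary. `pool_mean_differences()` pools per-study mean
differences $m_1 - m_2$ with variances $s_1^2/n_1 + s_2^2/n_2$ by inverse
variance; the random-effects model (the default) adds DerSimonian–Laird
$\tau^2$, and the 95% CI is `effect ± 1.96·SE`. Both fixed- and
random-effects models are provided because the source work describes both;
with $\tau^2 = 0$ they coincide exactly, which is asserted, and the whole
routine is cross-checked against an independent meta-analysis package.

`module_score_cells()` computes per-cell module scores two ways, because
the naming of the published procedure leaves the control-gene subtraction
ambiguous: the default subtracts the mean over control genes sampled
(`n_ctrl = 100` per module gene, seeded) from `n_bins = 24`
average-expression-matched bins — the convention of single-cell module
scoring — and `n_ctrl = 0` gives the plain set mean. Both modes separate
planted cell states (AUC ≥ 0.9 at 8-fold marker up-regulation, 500 cells).

## 6. Clustering stability and gene-set integration

`adjusted_rand_index()` is the Hubert–Arabie chance-corrected form computed
from the contingency table; it is relabeling-invariant, 1 exactly for
identical partitions, near 0 under independence, and matches an independent
implementation on random labelings. `stability_sweep()` operationalizes
"pick the resolution where stability starts to drop": at each grid point
(default 0.10–0.50 in steps of 0.05), a reference clustering at the base
seed is compared by ARI with `n_reseeds` (default 100) reseeded runs (seeds
`base_seed + i`, for auditability); the chosen resolution is the one
immediately before the first *strict* decrease in mean ARI (ties count as
non-decreasing; a tolerance is configurable and defaults to 0), and a
never-decreasing trace selects the last grid point with a flag. The
clusterer is a caller-supplied contract `(data, resolution, seed) →
labeling`; a k-nearest-neighbour + Louvain reference implementation ships
for convenience, but the sweep is algorithm-agnostic, and published ARI
values (e.g. "> 0.85") are descriptions of data, not selection parameters,
so they are not defaults. `overlap_coefficient()` and `pairwise_overlap()`
give the $|A \cap B| / \min(|A|,|B|)$ similarity used to integrate
leading-edge collections across studies.

## 7. The synthetic-data generators

Three generators give every stage inputs with known truth:

- `simulate_paired_counts()` — negative-binomial counts (mean–dispersion
  form, gene-wise dispersion constant by default) for a paired design in
  which every subject contributes one M-MDSC and one monocyte sample.
  Within-pair correlation comes from a shared lognormal subject factor;
  planted log2 fold changes (gamma-distributed magnitudes, random signs)
  apply symmetrically to the pair so library sizes stay comparable, and the
  exposed arm's fold changes are multiplied by `attenuation_factor`.
  Defaults mirror a small paired clinical cohort: 6 exposed and 12
  unexposed pairs, 2000 genes, 10% DE genes of mean |log2FC| 1, attenuation
  0.5, dispersion 0.1, and 2e6 expected library size — values a bulk
  RNA-seq practitioner would call realistic for sorted-cell studies; they
  were fixed once when the generator was written.
- `simulate_mixtures()` — nonnegative state signatures that are zero
  exactly off-guide (gamma-distributed otherwise, columns normalized to a
  common sum; see §4), Dirichlet(`alpha`) fraction columns, and additive
  Gaussian noise clipped at zero. Noise is Gaussian rather than NB because
  deconvolution operates on linear expression summaries, not raw counts.
- `simulate_cells()` — Poisson counts for cells with discrete states and
  disjoint per-state marker sets up-regulated `fold_up`-fold; cells of a
  state share one expected profile.

All three are bit-reproducible given a seed (asserted), and every stochastic
routine in the package takes an explicit seed and restores the caller's RNG
state.

**What passing tests do and do not show.** The generators emulate the
*statistical structure* each stage assumes — paired NB counts with a
multiplicative attenuation effect, guide-respecting linear mixtures,
separable discrete cell states. They deliberately do not emulate real
library-size distributions, empirical mean–dispersion trends, gene symbols,
doublets, or ambient contamination. Green tests therefore demonstrate that
the statistics are implemented correctly and recover planted truth under
their own model assumptions; they do not validate the biological claims on
real cohorts, which require the original (controlled-access) data.

## 8. Problem sizes, numerics, and limitations

The test suite and pipeline run at deliberately modest scale — thousands of
genes, tens of samples, hundreds of permutations or null iterations, and up
to a hundred simulation replicates per property — sizes chosen so the full
suite completes in minutes on one core while the Monte-Carlo assertions
retain comfortable margins; all of them are parameters, and production runs
can raise `n_iter`, `n_perm`, `n_reseeds`, or `n_restarts` freely.

Numerical conventions worth knowing: empirical p-values always use the
add-one convention and can never be zero; GSEA ties are broken by gene id;
NMF updates guard denominators with 1e-12 and the mask by projection;
fraction columns renormalize onto the simplex at output; BH adjustment
delegates to the standard step-up implementation after validating inputs.

Out of scope by design: dispersion estimation and GLM machinery for DE
(external tables are first-class inputs instead), phenotype-permutation
GSEA (requires sample-level expression), pathway knowledgebase content,
survival modelling on scores, batch correction, and the full single-cell
preprocessing stack (QC, doublet removal, integration, label transfer,
velocity). The deconvolution estimates only the guided states and does not
select an NMF rank.
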