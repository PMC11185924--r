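---
title: "Predicting drug sensitivity from tumor transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug sensitivity from tumor transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsense)
```

## The problem

Large pharmacogenomic panels measure, for hundreds of cancer cell lines, both
a basal (untreated) expression profile and the response to hundreds of
compounds, summarized as the area under the dose--growth-inhibition curve
(AUC; the higher the AUC, the more drug is needed to inhibit growth, i.e. the
more resistant the line). drugsense uses such a panel to learn, per drug,
which genes' expression marks sensitivity or resistance, and then scores any
tumor expression profile against every drug, producing a per-sample drug
ranking. Per-patient rankings can further be aggregated into one consensus
list per molecular subtype -- the setting that motivates the method is a rare
pediatric cancer where no tumor-matched drug-response training data exist,
so all training signal must come from pan-cancer panels.

## Training: drug--gene correlation profiles

For each drug $d$ and gene $g$, the Pearson correlation
$r_{gd} = \mathrm{cor}(x_g, \mathrm{AUC}_d)$ is computed across the cell
lines in which both are measured (pairwise-complete observations). Sorting
genes by $r_{gd}$ in descending order yields the drug--gene correlation
profile (DGCP): genes at the top are positively correlated with AUC
(expression marks resistance), genes at the bottom negatively (expression
marks sensitivity). The top and bottom windows of the DGCP (default 250
genes) are the drug's resistance and sensitivity biomarker sets.

Choices the data force, and how they are resolved:

* **Missing values** are excluded pairwise; a gene is retained only with at
  least `min_pairs` complete pairs (default 10, also the per-drug floor:
  drugs measured in fewer lines are skipped with a warning). The default is
  a configurable guess -- public panels are incomplete by nature and no
  canonical cutoff exists.
* **Ties** in correlation are broken by a stable sort on gene id, so
  retraining is bit-reproducible.
* **Lineage splits** (e.g. solid vs liquid panels) are the caller's
  responsibility: `build_library()` trains on whatever cell-line subset it
  is handed and records a free-text lineage label. Lineage annotation is
  metadata, not something the method can infer.
* **Gene identifiers** are matched exactly and case-sensitively. Symbol
  aliasing is data-dependent; inputs must share a namespace.

Two diagnostics accompany training. `pathway_anticorrelation_check()` asks
whether genes in the same pathway as a drug's target sit lower in the DGCP
than background genes (one-sided Mann--Whitney U): on real panels, target
pathways should be anticorrelated with AUC if the DGCP carries biology.
`biomarker_overlap_enrichment()` is a standard hypergeometric
over-representation test of a biomarker list against gene-set collections
(GMT input), with Benjamini--Hochberg correction and a q < 0.05 flag.

## Scoring: four directional GSEA tests and the G-score

A tumor profile is ranked from most to least expressed gene (restricted to
the library's gene universe). Against each drug's DGCP, four running-sum
(Kolmogorov--Smirnov) enrichment tests are computed with set size $s$
(default 250):

1. the $s$ most expressed tumor genes should fall near the DGCP **bottom**
   (sensitivity end) -- ranking by DGCP, expected enrichment score (ES)
   toward $-1$;
2. the $s$ least expressed tumor genes should fall near the DGCP **top** --
   ranking by DGCP, ES toward $+1$;
3. the DGCP's bottom-$s$ sensitivity biomarkers should be **up-regulated**
   -- ranking by tumor expression, ES toward $+1$;
4. the DGCP's top-$s$ resistance biomarkers should be **down-regulated** --
   ranking by tumor expression, ES toward $-1$.

The ES is the signed maximum deviation of the running sum in which hits
increment by $|r_i|^\alpha / \sum_{hits} |r_j|^\alpha$ and misses decrement
by $1/(N - n_{hit})$. The exponent $\alpha$ defaults to 0 (the classic
unweighted statistic); it is exposed as `es_weight` because the literature
uses both 0 and 1, and the robustness suite exercises both. On exact
$|max| = |min|$ ties the positive branch is taken, with a $10^{-12}$ epsilon
so that different summation orders cannot flip the sign.

**Permutation null.** Each test's p-value is empirical: the null
distribution of the ES is generated by shuffling a fraction (default 25%)
of the gene labels of the ranking and recomputing the ES, `n_perm` times
(default 10,000). "Shuffling 25% of the labels" is implemented as drawing a
uniformly random 25% subset of positions and cyclically deranging the labels
at those positions in a random order, so every selected label actually
moves; the ranking's values stay attached to positions. The shuffled subset
is resampled every permutation. One-sided p-values use the add-one rule
$p = (1 + \#\{\text{null at least as extreme}\}) / (1 + n_{perm})$, so
$p \geq 1/(n_{perm}+1) > 0$.

Tests 1--2 share the DGCP ranking and tests 3--4 the tumor ranking, so each
permutation shuffles each ranking once and evaluates both of its sets on it.
This halves the work and -- more importantly -- yields *joint* null
ensembles from which the dependence between the tests can be estimated.

A calibration subtlety worth knowing: with partial (25%) shuffling the null
ranking stays close to the observed one, so under a global null the
empirical p-values are *under-dispersed* (concentrated around 0.5) rather
than uniform. That is by construction -- the method compares drugs within a
sample, where a common conservative transformation of all p-values is
harmless. Exact uniformity holds in the full-shuffle limit
(`shuffle_fraction = 1`), which is what the calibration tests use.

**Combination.** The G-score is the geometric mean
$g = (p_1 p_2 p_3 p_4)^{1/4}$; smaller means predicted more sensitive, and
drugs are ranked per sample in ascending order (ties by drug id). Because
the four tests are correlated, Brown's method is computed as well: with
$X = -2\sum_i \ln p_i$, $X$ is referred to a scaled $\chi^2$ with
$c = \mathrm{var}(X)/(2\,E[X])$ and $df = 2\,E[X]^2/\mathrm{var}(X)$, where
$E[X] = 8$ and $\mathrm{var}(X) = 16 + 2\sum_{i<j}\mathrm{cov}_{ij}$. The
covariance of the $-2\ln p$ statistics is estimated from the joint
permutation ensembles (null ES values rank-transformed to uniform p within
each test, then $-2\ln$); the two cross-ranking covariances are ~0 by
construction. Zero covariance recovers Fisher's method exactly; a
degenerate covariance falls back to Fisher with a warning. In practice the
Brown-based and geometric-mean-based rankings nearly coincide (Spearman
> 0.99 on the synthetic cohort), so the default ranking uses the G-score.

**Cost.** Permutation nulls dominate the runtime, so they run in compiled
code driven by R's RNG (fully reproducible from `set.seed()` / the `seed`
parameter). Scoring one 2,000-gene profile against 30 drugs at
`n_perm = 1000` takes about 2 seconds on one core; the 10,000-permutation
default scales linearly.

## Rank aggregation

Per-patient rankings are combined into one top-$k$ consensus per subtype by
minimizing the mean Spearman footrule distance: for each input list, the
distance is $\sum |pos_{cand} - pos_{input}|$ over the union of the
candidate and the input's top-$k$, with absent items at position $k+1$; the
objective is the mean over input lists. The optimizer is Cross-Entropy
Monte Carlo: a universe-by-$k$ column-stochastic matrix (uniform start) is
sampled (`n_samples` = 10x universe size), the best `rho` = 10% of sampled
lists re-estimate the matrix, smoothed as
$P \leftarrow 0.7\,P_{elite} + 0.3\,P$; stopping after 200 iterations or 15
without improvement. These defaults follow the common rank-aggregation
practice; the source publication names only the algorithm.

The best-ever candidate is finally polished by a deterministic
transposition/exchange local search. Rationale: the probability matrix can
collapse prematurely onto an order one adjacent transposition away from the
optimum; the polish removes such residues, can only improve the objective,
and keeps the guarantee that aggregating identical input lists returns
exactly their shared top-$k$ with objective 0. On small instances (6 items,
$k = 3$) the optimizer matches exhaustive enumeration in ~99% of seeds.

`aggregate_bottom()` reverses every list first, giving the consensus of the
*worst* drugs (a useful negative-control list); `subtype_specific()` splits
two consensus lists into shared and subtype-only drugs, preserving order.

## Validation: normalized PPV curves

Gold standards label (sample, drug) pairs sensitive/resistant/unknown:
either from an AUC table (default rule: sensitive iff AUC at or below the
per-drug 5% quantile -- the exact calling rule used on public panels is not
recoverable, so the rule and `q` are configurable and recorded in the
object's provenance) or from clinical-style categorical calls (CR/PR
sensitive, SD/PD resistant). Scored pairs are sorted ascending by G-score
and the cumulative positive predictive value is computed at each percentile;
dividing by the prevalence of sensitive pairs (the PPV of a random ordering)
gives the normalized curve, which always terminates at 1 and is invariant
under monotone transforms of the score. Unknown pairs are excluded rather
than counted as false positives. `cross_control_evaluation()` scores the
same samples with a matched and a mismatched (e.g. label-shuffled or
cross-lineage) library and returns both curves.

## The synthetic benchmark

`simulate_benchmark()` generates the study conditions every statistical test
in the package runs on. Each drug $d$ carries a latent per-cell-line
response factor $u_{dc} \sim N(0,1)$ with $\mathrm{AUC}_{dc} = 10 + u_{dc}$
(clamped at zero). A gene planted as a biomarker for drugs $D(g)$ gets

$$ x_{gc} = \frac{\sum_{d \in D(g)} s_{gd}\,\beta\,u_{dc} + \sigma\,e_{gc}}
   {\sqrt{k_g\,\beta^2 + \sigma^2}}, \qquad e_{gc} \sim N(0,1), $$

with sign $s_{gd} = +1$ for resistance and $-1$ for sensitivity and
$k_g = |D(g)|$; unplanted genes are plain $N(0,1)$. Every gene is therefore
marginally standard normal and the per-gene correlation with drug $d$'s AUC
is exactly $s_{gd}\,\beta/\sqrt{k_g \beta^2 + \sigma^2}$, so the
signal-to-noise ratio $\beta/\sigma$ directly controls biomarker
recoverability ($\approx 0.89$ per singly-planted gene at $\beta/\sigma = 2$,
the default). This latent-factor construction was chosen over generating
AUC as a sum over planted genes' expression: the summed construction dilutes
each gene's correlation by $1/\sqrt{2 n_b}$ (capping it at 0.1 for 50
biomarkers per direction), which would make individual biomarkers
statistically invisible -- contradicting the premise that biomarkers are
genes visibly correlated with response.

Defaults are the benchmark conditions used throughout the tests: 2,000
genes, 60 cell lines, 30 drugs, 50 biomarkers per direction, $\beta = 2$,
$\sigma = 1$. At this scale 3,000 planted slots exceed the gene pool, so
planted sets overlap across drugs (always disjoint within a drug); the
$k_g$-aware standardization keeps overlapping genes well-behaved. Disjoint
planting is used automatically when feasible and can be demanded
explicitly.

`simulate_cohort()` adds tumor samples: i.i.d. standard-normal background
plus a `shift` (default 2 background SDs) added to the sensitivity
biomarkers -- and subtracted from the resistance biomarkers -- of the drugs
designated effective for the sample's subtype. Defaults: two subtypes of 20
patients, each designated 20% of the drug panel (6 of 30). The designation
fraction was fixed by a design-stage power calculation: the no-signal
normalized-PPV band [0.7, 1.3] used in the negative control needs a
prevalence around 0.2 to have decent coverage on a 1,200-pair cohort, while
leaving the matched signal threshold (3x random, maximum 5x at this
prevalence) comfortable headroom.

What the generator does *not* emulate: RNA-seq marginal distributions
(irrelevant to a rank/correlation-based method), lineage or batch structure,
realistic dose-response curve shapes, and inter-patient heterogeneity beyond
i.i.d. noise. Passing tests on this benchmark demonstrate that the
machinery recovers planted signal at a known signal-to-noise ratio; they say
nothing about biological validity on real panels. One consequence of the
simple cohort model matters for interpretation: patients of a subtype are
near-replicates (they share the designated biomarker shifts), so pair-level
statistics on the cohort have far fewer effective degrees of freedom than
the pair count suggests. The negative-control band is therefore evaluated
on the stable region of the curve (mean over percentiles >= 10) rather than
on a single early bin.

## Numerical choices and degenerate inputs

* Empirical p-values carry the $1/(n_{perm}+1)$ floor; the G-score rejects
  $p \le 0$.
* ES sign ties resolve positive (epsilon $10^{-12}$); gene-set/ranking
  degeneracies (empty intersection, set covering the whole ranking) are
  errors, not silent results.
* Profile-ranking ties break on gene id; all-constant profiles warn and
  fall back to lexicographic order.
* Duplicate gene rows collapse by mean on read (with a warning); duplicate
  ids elsewhere are errors.
* DGCP libraries serialize correlations as 17-significant-digit decimal
  text, which round-trips IEEE doubles exactly; manifests carry a format
  version and truncated per-drug tables fail loudly.
* Biomarker windows larger than the DGCP clamp with a warning; windows
  overlapping (2s > genes) warn that the sensitivity/resistance partition is
  not disjoint.
* All stochastic steps (permutation nulls, CE sampling, generators) are
  driven by R's RNG and accept explicit seeds; scoring a cohort reuses the
  same seed per sample so identical profiles get identical rankings.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at the
benchmark scale above (training 30 DGCPs on 2,000 x 60; scoring 40 tumors
at `n_perm` = 1000, set sizes 100/250/500) plus 100 reduced-scale end-to-end
replicates (400 genes, 8 drugs, 10 patients, `n_perm` = 200, $k = 3$
consensus) for the subtype-recovery rate, and oracle comparisons at the
sizes stated in the test names. These sizes were chosen so the entire
battery completes in minutes on a single core while keeping every check at
the scale where its statistical claim is meaningful.

## Known limitations

* Training assumes expression and response share pre-harmonized cell-line
  ids and gene namespaces; no identifier mapping is attempted.
* The min-pairs filter is a plausible, configurable stand-in for an
  unpublished training filter; retrained drug counts on real panels will
  depend on it.
* Partial-shuffle p-values are comparable within a sample but are not
  globally calibrated (see above); no cross-drug FDR is computed because the
  method ranks rather than thresholds.
* The Brown covariance is estimated from permutation ensembles of the same
  size as the null; with very small `n_perm` the estimate is noisy and the
  geometric mean is the more stable ranking key.
* The CE optimizer is stochastic; for small universes
  `exhaustive_aggregate()` is the exact reference, and the polish step only
  guarantees local optimality.
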