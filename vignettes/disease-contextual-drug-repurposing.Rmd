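---
title: "Disease-contextual drug similarity networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-contextual drug similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsimnet)
```

## The model

`drugsimnet` scores drugs for repurposing against a disease characterized by
a case/control expression dataset. The premise is that a drug is a plausible
candidate when the biological functions its targets participate in are
transcriptionally dysregulated in the disease, and when that evidence is
reinforced by functionally similar drugs. The pipeline has four stages.

**1. Differential-expression scoring.** Expression is z-score normalized per
gene across all samples, then each gene gets a two-tailed t-test p-value
(case vs control) and a DE score $DE_x = |\Phi^{-1}(1 - p_x)|$. The t-test
is invariant to per-gene affine rescaling, so normalization does not change
DE scores; it is kept because it puts exported matrices on a common scale
and is the conventional preprocessing for heterogeneous expression series.

**2. Drug/gene-set bipartite network.** A drug $D$ (its target set) and a
functional gene set $G$ are connected with weight
$W_{DG} = J_{DG} \cdot \mathrm{med}\{DE_x : x \in D \cap G\}$, where
$J_{DG}$ is the Jaccard index of the two sets. The Jaccard factor measures
how specifically the drug's targets realize the function; the median DE
factor injects the disease context — an overlap among transcriptionally
quiet genes contributes nothing.

**3. Projection.** The drug-drug functional similarity matrix is
$A = W W^{\top}$ with the diagonal zeroed (no self-links), i.e.
$S_{ab} = \sum_j W_{aj} W_{bj}$ over all shared gene sets. Edges exist
exactly where $S_{ab} > 0$; no additional sparsification threshold is
applied, since $S_{ab} = 0$ precisely when two drugs share no positively
weighted set.

**4. Propagation and significance.** $A$ is column-normalized into a
transition matrix $T$ and the random walk with restart
$v^{t+1} = (1-r) T v^t + r v^0$ is iterated from the uniform seed to its
fixed point. The stationary $v_i$ is the drug's centrality. Significance
comes from a gene-level bootstrap: DE scores are resampled with replacement
from the observed pool and reassigned to genes, stages 2–4 are rebuilt, and
the empirical p-value is the fraction of replicates whose centrality reaches
the observed one, followed by Benjamini–Hochberg adjustment and a strict
FDR < 0.1 candidate call.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| target-set filter | 4–499 targets | drops degenerate ($\le 3$) and promiscuous ($\ge 500$) drugs before any dataset-specific step |
| gene-set filter | 6–99 genes | avoids overly narrow or broad functional categories |
| restart probability $r$ | 0.9 | the ranking is empirically insensitive over $r \in [0.1, 0.9]$ (the suite checks top-20 overlap and Spearman correlation across that range); larger $r$ also converges faster |
| convergence tolerance | 1e-10 (L1) | L1 pairs naturally with probability vectors; with $r = 0.9$ the iteration contracts by factor $1-r = 0.1$ per step, so convergence takes ~12 iterations |
| max iterations | 10,000 | far above need; non-convergence is flagged, not fatal |
| bootstrap replicates $B$ | 1000 | p-value granularity is $1/B$; the test suite and acceptance script use $B = 200$ at their reduced problem sizes |
| FDR threshold | 0.1 | strict inequality: a drug at exactly 0.1 is not a candidate |

## Numerical and procedural choices

- **t-test variant.** Welch (unequal variances) by default: unpaired,
  heterogeneous cohorts rarely satisfy equal variances. The pooled-variance
  test is available (`var_equal = TRUE`).
- **Clamping.** p-values are clamped to $[10^{-300}, 1 - 10^{-16}]$ before
  the quantile transform, which is otherwise $\pm\infty$ at the endpoints.
  Genes with zero variance in both groups get $p = 1$ (no evidence) when
  the group means agree and $p = 0$ (clamped) when they differ.
- **The transform is asymmetric by definition.** $z = \Phi^{-1}(1-p)$ maps
  $p$ near 1 to a large *negative* $z$, and the DE score $|z|$ is then
  large. This is the definition as stated and is kept as the default; the
  conventional symmetric two-tailed transform
  $z = \Phi^{-1}(1 - p/2)$ is available via `symmetric = TRUE`. In practice
  the asymmetry matters little: under the null, $p$ near 1 is as rare as
  $p$ near 0, and a planted signal concentrates $p$ near 0.
- **Median convention.** For even-sized overlaps the median is the midpoint
  of the two central values.
- **Unmeasured genes.** Overlap genes without an expression measurement are
  excluded from the median; if no overlap gene is measured the edge weight
  is 0 — an unmeasurable contextual weight should not create contextual
  edges. The Jaccard factor always uses the full set sizes.
- **Isolated drugs.** Drugs with an all-zero row/column in $A$ make the
  column normalization undefined and cannot receive propagation evidence;
  they are removed before normalization and reported with centrality 0 and
  $p = 1$. The same rule, applied per replicate, keeps the bootstrap null
  matrix rectangular and is conservative for the empirical p-value.
- **Exact zeros in p-values.** The counting estimator can return 0, which
  is kept as the default; an add-one estimator $(k+1)/(B+1)$ is available
  (`pseudocount = TRUE`) for workflows where downstream treatment of exact
  zeros is degenerate.
- **Reproducibility.** Each bootstrap replicate draws from its own sub-seed
  derived once from the master seed, so results are independent of
  execution order; two runs with identical inputs and seed produce
  byte-identical result tables (the suite asserts this).
- **Duplicate expression rows** collapse by mean — deterministic and
  order-independent. Gene identifiers are matched by exact string equality
  after whitespace trimming; alias resolution is out of scope.
- **Dense linear algebra.** At the intended scale (a few thousand drugs)
  dense `tcrossprod` and dense iteration are simpler and fast enough; the
  closed-form solve $v = r(I - (1-r)T)^{-1} v^0$ exists as an analytic
  cross-check, not the production path.

## What the synthetic benchmark emulates

`generate_benchmark()` produces the three input kinds with a planted,
recoverable signal:

- **Expression**: i.i.d. $N(0,1)$ noise per gene and sample; a designated
  set of "disease" genes gains a mean shift of `effect_size` SD units
  (default 2.5) in the case group (default 20 + 20 samples, 2,000 genes).
  Gaussian noise makes the t-test layer's null calibration interpretable.
- **Gene sets**: 300 sets of 8–40 genes drawn uniformly from the gene
  universe.
- **Drugs**: every drug — true and decoy alike — anchors on 2 random gene
  sets and draws its 5–30 targets from their member genes, so each drug has
  genuine functional-set overlap and the drug–drug network is connected.

The key design choice is *where the signal is planted*. The true drugs are
an arbitrary designation among identically constructed drugs; the disease
genes are defined as the union of the true drugs' anchor-set genes (padded
with random genes up to `frac_dysregulated`, default 0.15). Consequently:

- at `effect_size = 0` true and decoy drugs are statistically exchangeable
  *by construction* — the designation touches nothing but the expression
  shift — so the pipeline's p-values can be checked for calibration and its
  AUROC against the designated drugs hovers around 0.5;
- at positive effect sizes the signal reaches the true drugs only through
  the bipartite drug/gene-set path (their anchor sets become "hot":
  high-median-DE overlaps), exercising the full network construction rather
  than any score shortcut.

An earlier design that gave true drugs a structurally distinct target pool
was rejected because the designated drugs remained identifiable from
topology alone at zero effect, which breaks the null calibration the
benchmark exists to verify.

What the generator does **not** emulate: transcriptome covariance
structure, batch effects, dropout, or realistic target-set size
distributions. Passing the planted-recovery tests therefore shows the
pipeline propagates a clean contextual signal end-to-end; it does not
certify performance on real cohorts, where DE scores are correlated across
genes and catalogs are far sparser.

## Problem sizes used by the automated checks

The test suite and acceptance script run the generator defaults (100 drugs,
300 sets, 2,000 genes, 20/20 samples) for signal recovery and restart
robustness, a 50-drug/150-set variant with `effect_size = 0` and $B = 200$
for null calibration (10 seeds each), and random matrices up to 200 nodes
for the projection and walk oracles. These sizes keep a full check under a
minute per section on one CPU while leaving every stage of the method
load-bearing.

## Known limitations

- The bipartite weights inherit the t-test's assumptions; strongly
  non-Gaussian or small-$n$ cohorts would be better served by a moderated
  statistic, which is out of scope here.
- The bootstrap resamples DE scores independently across genes, ignoring
  gene-gene correlation; on real data the null is therefore somewhat
  anti-conservative for drugs targeting co-expressed modules.
- Centrality is relative to the supplied drug catalog: adding or removing
  drugs changes the transition matrix and hence all scores.
- Identifier harmonization (gene aliases, drug synonyms) must happen before
  the data enter the pipeline.
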