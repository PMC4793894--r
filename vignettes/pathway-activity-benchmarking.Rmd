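---
title: "Pathway activity scoring and consistency benchmarking: models and choices"
author: "pathwaybench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activity scoring and consistency benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaybench)
```

# The problem

Given case/control gene expression data and a collection of pathways, a
pathway activity method decides which pathways behave differently between
the groups. Methods divide into two families: those that use only the
pathway's gene list (overrepresentation tests, enrichment statistics,
deregulation scores) and those that also exploit the pathway's *topology*
— the signed, directed graph of activation and inhibition edges among its
genes. This package implements six representative scorers from both
families behind one interface, together with fixed preprocessing rules, a
cross-dataset consistency score, and synthetic data generators, so the
entire comparison can be run and tested end to end without any external
download.

All methods share notation: a pathway $G$ contains $p$ genes
$g_1,\dots,g_p$; a study has $m$ samples split into cases $A_C$ and
controls $A_R$; $de(i) \in \{0,1\}$ marks gene $i$ as differentially
expressed (DE).

# Preprocessing

Three fixed rules precede every scorer:

* **Scaling.** Intensities are transformed as $\log_2(x+1)$; adding one
  keeps zero at zero and avoids negative values without distorting the
  intensity range (`logScale()`). Whether a scorer sees scaled or
  unscaled input follows the conventions below.
* **Probe collapsing.** A probe mapping to several genes is removed; of
  several probes mapping to one gene, the one with the highest
  across-sample variance is kept, ties broken by input order
  (`collapseProbes()`).
* **DE detection.** `detectDE()` runs a per-gene two-sided Welch t-test
  with $\Delta(i) = \bar{x}_{case} - \bar{x}_{ctrl}$ (a log2 fold change
  on scaled data) and converts p-values to FDR with the
  Benjamini–Hochberg step-up (`bhFDR()`, a validating wrapper over
  `stats::p.adjust`). A gene is DE when FDR < 0.05. The detector is
  pluggable (`detector` argument) because moderated-variance detectors
  such as limma or ROTS are drop-in alternatives for the same interface;
  the Welch default keeps the package self-contained and assumption-light.
  Genes with zero variance in both groups get p = 1: without
  within-group variability the t model has nothing to test. No
  fold-change filter is applied on top of the FDR cutoff.

Significance is *always* FDR < 0.05 per method, with p-values converted
by `bhFDR()` where a method produces raw p-values.

# The six scorers

## Perturbation propagation (SPIA-style), `runSpia()`

Two independent evidence channels are combined. The first is the
hypergeometric upper tail $P_{NDE}$: the probability of observing at
least as many DE genes in the pathway under random placement
(`pNDE()`). The second propagates signed perturbation through the graph:

$$PF(i) = \Delta(i) + \sum_{k \in parent(i)} \beta_{ki}\,
  \frac{PF(k)}{n_{child}(k)},$$

with $\beta_{ki} = +1$ for activation and $-1$ for inhibition; only DE
genes carry their log2 fold change, all other (and unmeasured) pathway
genes enter with $\Delta = 0$ but remain in the graph so the topology is
preserved. The net (inherited) perturbation is
$PB_{tot} = \sum_i (PF(i) - \Delta(i))$. `perturbationFactors()` solves
the recursion exactly as a linear system $(I - B)\,PF = \Delta$ and
checks the residual; on cyclic graphs where $I - B$ is singular it falls
back to $PF = \Delta$ and flags the pathway degenerate. $P_{PB}$ is a
bootstrap tail: the multiset of nonzero $\Delta$ values is re-placed on
uniformly random nodes and $PB_{tot}$ recomputed; the p-value is
two-sided around the null median (the convention of the reference SPIA
software), smoothed as $(1 + \#\{\cdot\})/(n_{boot}+1)$. The combined
score is $c - c\ln c$ with $c = P_{NDE} P_{PB}$, the tail probability of
a product of two independent uniforms.

## Centrality-weighted overrepresentation (CePa-ORA style), `runCepa()`

For each pathway, $S = \sum_{i \in G} centrality(i)\,de(i)$ under six
weighting criteria: equal weight, in-degree, out-degree, directed
unnormalised betweenness, in-reach and out-reach (the length of the
longest shortest path toward roots resp. leaves). Reach criteria count
*edges*, not nodes — a documented choice where either reading is
defensible. The null redraws $|DE|$ genes uniformly from the measured
background; a pathway is significant when *any* of the six criteria has
FDR < 0.05 (the any-of-six rule). Using several criteria avoids
favouring particular shapes: a chain maximises reach weights, a hub
maximises degree weights.

## Simplified network statistic (NetGSA-style), `runNetgsa()`

Each sample's expression over the measured pathway genes is modelled as
$e_j = \Lambda \gamma_j + \epsilon_j$, where the influence matrix
$\Lambda = (I - \rho A)^{-1}$ accumulates signed effects along directed
paths ($A[i,k]$ is the sign of edge $k \to i$). On an acyclic graph with
$\rho = 1$, $\Lambda[i,k]$ is exactly the signed path-sum from $k$ to
$i$; on cyclic graphs $\rho$ is the damping (default 0.9) divided by the
spectral radius so the series converges. The latent effects are
estimated by least squares and the pathway statistic is
$S = \sum_{i \in G} [\Lambda(\bar\gamma_C - \bar\gamma_R)]_i$, tested by
two-sided sample-label permutation. The original formulation estimates
the latent variables with a mixed-integer model; the least-squares +
permutation route here is a deliberate simplification and every result
row carries `simplified_inference = TRUE`. Note that when $\Lambda$ is
invertible the statistic coincides with the summed group mean
difference; the influence model matters for the structure of the
estimation contract, and the permutation null supplies the inference.

## Jackknifed Fisher / EASE score (DAVID-style), `runEase()`

The plain Fisher upper tail asks how surprising $k$ DE genes in a
pathway are; the EASE variant removes one DE hit ($k \mapsto
\max(k-1,0)$, with $k=0 \mapsto 1$) before taking the tail, penalising
pathways whose significance rests on a single possibly false-positive
gene. The single-removal reading is implemented (rather than averaging
over leave-one-out iterations): it is the published EASE score, and the
two readings coincide in the equal-weight hypergeometric setting. The
EASE p-value always dominates the plain Fisher tail.

## Enrichment analysis (GSEA), `runGsea()`

Genes are ranked by decreasing signal-to-noise ratio
$d(i) = (\bar{x}_C - \bar{x}_R)/(s_C + s_R)$ with each group sd floored
at $0.2\,|\bar{x}|$ (the classic stabilisation; the ranking metric is
pluggable, and ties break lexicographically so ranking is
deterministic). The enrichment score is
$S = \max_r |P_{hit}(r) - P_{miss}(r)|$, where $P_{hit}$ accumulates
member genes weighted by $|d|^u$ and $P_{miss}$ accumulates non-members
uniformly, evaluated after every rank. Default $u = 1$; $u = 0$ makes
the score rank-only and invariant under monotone transforms of $d$.
Significance comes from re-ranking under uniformly drawn sample-label
permutations (1000 by default, identity not excluded), and set-level FDR
is obtained by Benjamini–Hochberg on the permutation p-values — simpler
than the normalised-score FDR of the reference implementation, and
consistent with the package-wide FDR rule. By convention GSEA consumes
unscaled intensities.

## Principal-curve deregulation (Pathifier-style), `pathifierScores()`

Samples reduced to a pathway's genes form a cloud in $p$ dimensions; a
smooth one-dimensional *principal curve* through the cloud orders
samples along an inferred progression. A sample's deregulation score is
the arc-length distance between its projection and the projection of the
control centroid, so the control centroid scores 0 by construction.
`fitPrincipalCurve()` implements the projection/smoothing iteration:
initialise on the first principal-component segment, project, reorder,
smooth each coordinate against the arc parameter, re-parameterise by
cumulative arc length, and stop when the mean squared projection
distance changes by less than `tol` (or immediately when the initial
segment already interpolates the cloud, which makes exactly collinear
data a closed-form case). The coordinate smoother is locally weighted
linear averaging (`stats::lowess`, `iter = 0`, span 0.75 by default): a
plain running mean at a practical span biases the curve off any
noticeably bent cloud by $O(f''\,w^2)$, which already on a gently curved
arc exceeds the noise level, while the locally weighted fit tracks it
within noise. Span, `maxIter` (10) and `tol` (1e-4) are exposed.

Genes are z-scored over *all* samples before fitting. Standardising by
control statistics alone — the other natural choice — imprints a random
offset of norm $\approx \sqrt{2p/n_R}$ on the case cloud (the controls
are centred by their own estimated means, the cases are not), which at
typical sample sizes inflates the false-positive rate of the group
comparison several-fold; measured on control-only null splits, the
control-based variant called 27% of pathways at p < 0.05 against 5.3%
for all-sample z-scoring. At least 4 controls are required: the control
centroid and the curve are too poorly determined below that. Group-level
calls (`pathifierGroupTest()`) are a Welch t-test of case versus control
scores per pathway with FDR across pathways. The original tool's
stabilisation layers (PCA pre-reduction, variance filtering) are out of
scope.

# Scaling conventions

GSEA consumes unscaled data; the network statistic and deregulation
scoring consume scaled data; the DE-list methods (SPIA, CePa, DAVID)
have no recommendation and can be run on either form (`listInput` in
`runAllMethods()`), which changes their DE lists and hence their calls.
These per-method conventions are enforced inside the pipeline regardless
of what form a dataset arrives in.

# The consistency score

A method is useful when it reproduces findings across comparable studies
without inventing findings in data that contain none. For $l$ real
datasets and a batch of artificial null datasets,

$$score = \frac{1000}{T} \sum_{h=\lceil l/2 \rceil}^{l}
  \frac{\beta(h)\,(h - \lceil l/2 \rceil + 1)^2}{(\alpha + 1)^2},
  \qquad T = P\,(l - \lceil l/2 \rceil + 1)^2,$$

where $\beta(h)$ counts pathways significant in exactly $h$ real
datasets, $\alpha$ is the mean number of significant pathways on the
artificial data (false positives; +1 avoids division by zero), and $P$
is the number of tested pathways. Findings below a majority of datasets
contribute nothing; reproducibility is rewarded quadratically; $T$ puts
studies with different $l$ on a common $[0, 1000]$ scale (with $P = 86$
pathways, $T = 1376$ for $l = 6$ and $T = 774$ for $l = 4$); the factor
1000 keeps typical values readable. $\alpha$ may be fractional. The
score is 1000 exactly when every pathway is found in every real dataset
with no false positives, is monotone in every $\beta(h)$ and
antimonotone in $\alpha$ — all of which the test suite checks.

# Synthetic data: what it emulates, and what not

`simulateExpression()` draws per-gene baselines from a normal with
location 6 and scale 1 on the log2 scale (a typical microarray intensity
range), adds a fixed log2 shift to the case samples of `nDe` randomly
chosen genes plus Gaussian noise (sd 0.5), and returns intensities
$2^x - 1$ with the truth attached. Two presets encode the two study
regimes the benchmark targets: `"large"` (1500 DE genes at shift 1.5 —
the cancer-like setting with thousands of DE genes) and `"small"` (15 DE
genes at shift 0.6 — the diabetes-like setting where fewer than 20 genes
pass the FDR cutoff). `simulatePathways()` builds random DAGs by
topological-order edge sampling (cyclic graphs optional), with a
configurable inhibition fraction, drawing gene ids from the expression
universe so pathway/DE overlap is controllable.
`makeArtificialNulls()` reproduces the negative-control construction:
keep only control samples and relabel them by independent uniform splits
— heterogeneity is preserved, group signal is removed by construction.
`injectPathwaySignal()` adds a log2 shift to the case samples of a
chosen pathway's genes, enabling parameter-recovery experiments.

The generators do **not** model probe-level noise, batch effects, paired
designs, or correlated expression within pathways. Passing tests on this
synthetic data therefore demonstrate the *statistical machinery* —
calibration under the null, recovery of planted signal, reproducibility
scoring — not performance on real microarray cohorts, where
heterogeneity, annotation error and correlation structure are harsher.

# Numerical choices

* Permutation/bootstrap p-values are smoothed,
  $p = (1+\#)/(n+1)$, so they are never 0 and never below $1/(n+1)$.
  Defaults: 999 permutations, 2000 bootstrap replicates, seeds always
  explicit function arguments, never global state.
* The perturbation solve requires its residual to be at most
  $10^{-10}(1 + \lVert\Delta\rVert)$; reciprocal condition numbers below
  $10^{-12}$ trigger the degenerate fallback (propagation) or an error
  advising smaller damping (influence matrix).
* BH conversion, hypergeometric tails, t-tests, graph distances and
  betweenness are delegated to `stats` and `igraph`.
* Sorting of result tables by `(method, fdr, pathway_id)` and
  lexicographic tie-breaks in ranking make reruns with the same seed
  byte-identical.

# Benchmark problem sizes

The negative-control benchmark (`runArtificialNullBenchmark()`) uses a
pool of 20 homogeneous control samples over 500 genes and 20 pathways;
ten independent splits (five analysed as unscaled, five as scaled input
for the DE-list methods) are scored by all six methods with 199
permutations and 499 bootstrap replicates, and the ten outcome sets are
randomly halved into "real" and "artificial" roles for the consistency
score. The test suite's calibration studies use 200 null draws at 199
permutations, and the recovery study uses 20 replicates of a
2000-gene, 10+10-sample dataset with one injected pathway among 20.
These sizes were chosen so each study estimates its quantity stably
while the whole suite stays quick to run; all are arguments, not
constants.

# Known limitations

* The Welch default is less powerful than moderated-variance detectors
  on small samples; plug in a different detector where that matters.
* The network statistic's least-squares route forfeits the original
  mixed-model shrinkage; with an invertible influence matrix its
  observed statistic reduces to a mean-difference sum.
* The principal curve uses a fixed-span smoother without the original
  tool's stabilisation layers, so very small pathways (3–5 genes) give
  noisy curves.
* Per-sample deregulation FDRs are not produced; only group-level calls
  are, via the Welch conversion.
* Pathway nodes are single genes; compound or complex nodes must be
  flattened upstream.
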