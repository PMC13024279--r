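---
title: "Topology-integrated hubness scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-integrated hubness scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tihs)
library(dplyr)
```

## The problem

When a tumour becomes resistant to a therapy, its transcriptome rewires and
the interaction network induced by the differentially expressed genes (DEGs)
acquires new structural "hubs" — genes that sit in topologically central,
influential positions. Such hubs are attractive targets for drug
repurposing: an approved drug that potently inhibits an upregulated hub may
resensitize the resistant state. The difficulty is that "hubness" is
ambiguous — degree, betweenness and other centralities disagree, and
single-metric hub lists reproduce poorly across datasets.

This package formalizes hubness as a single continuous score, the
**Topology-Integrated Hubness Score (TIHS)**, and chains it to a signed
drug-ranking scheme with a multi-tier false-positive filter, a statistical
validation suite, and a synthetic generator with planted ground truth so
that every step can be exercised offline.

## The model

### Network construction

DEGs are selected at adjusted $p < 0.05$ (strict) and
$|\log_2 \mathrm{FC}| \ge 1$ (inclusive). Interactions are restricted to
high-confidence links (combined confidence $\ge 0.7$, the conventional
STRING high-confidence level), and the network is the induced subgraph on
the DEG symbols. By default only the largest connected component (LCC) is
retained: eigenvector centrality is ill-defined across disconnected
components (the principal eigenvector concentrates on one component and
assigns structural zeros elsewhere), and published node/edge counts for
networks of this kind are reported as single connected networks. The
`restrict_to_lcc = FALSE` escape hatch computes on the full graph instead.
Isolated DEGs carry no usable topology; they are excluded from scoring and
listed in `$excluded_degs`.

### Five centralities

For every node we compute, raw and unnormalized:

* **degree** — direct interaction count;
* **betweenness** — unnormalized shortest-path betweenness on the
  unweighted graph (confidences are ignored for path finding, the
  CytoHubba convention);
* **eigenvector** — principal eigenvector of the binary adjacency matrix,
  L2-normalized;
* **MCC** (maximal clique centrality) —
  $\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$,
  enumerated exactly;
* **EPC** (edge percolated component) — Monte-Carlo percolation: in each
  realization a single threshold $t \sim U(0,1)$ is drawn, every edge with
  confidence $< t$ is deleted, and a node scores the fraction of the
  network it can still reach; EPC is the average over realizations.

Raw values are deliberately left unnormalized because the downstream
Z-scoring absorbs any per-metric affine transformation; this invariance is
itself enforced by a test (TIHS is reproduced to $10^{-9}$ after arbitrary
positive affine transforms of any metric column).

### Normalization, weights, TIHS

Each metric column $j$ is standardized with the population standard
deviation, $Z_{ij} = (X_{ij} - \mu_j)/\sigma_j$, and shifted to be strictly
positive, $Z'_{ij} = Z_{ij} - \min_i Z_{ij} + 0.001$, so every column has
minimum exactly $0.001$. The shift is written in some descriptions as
"$Z + \min Z + 0.001$", which cannot avoid negative values when
$\min Z < 0$; subtracting the minimum is the only reading consistent with
the stated purpose and is what this package implements.

Metric weights $W_j$ with $\sum_j W_j = 1$ come in two modes:

* `std_share` (default): each **raw** column is first min–max rescaled to
  $[0,1]$ and $W_j = \sigma_j / \sum_k \sigma_k$ on the rescaled columns.
  Computing the $\sigma$ share on Z columns would force $\sigma = 1$ and
  equal weights, contradicting the observation that degree and betweenness
  dominate; computing it on raw columns would let MCC's factorial scale
  dominate by units alone. The min–max rescaling is the only variance share
  that is simultaneously unit-free and non-degenerate.
* `pca_loading`: the absolute PC1 loadings of the Z matrix, normalized to
  sum 1, with PC1 sign-aligned so its largest-magnitude loading is
  positive (eigenvector sign must be pinned for reproducibility).

Then $\mathrm{TIHS}_i = \sum_j W_j Z'_{ij}$ — strictly positive, and
strictly monotone in any single metric when the weights concentrate on it.
Weight vectors from several training datasets are combined by
`average_weights()` (arithmetic mean, renormalized) and their concordance
is assessed by `cosine_stability()` (cosine of unit-normalized vectors,
flagged below 0.98).

### Drug scoring and tiers

For a drug $d$ with matched network targets $t$ (matched = present in the
network; targets outside the network have no defined topology and
contribute nothing):

$$\mathrm{Total}_d = \sum_t \sum_j
  \frac{\log_2\mathrm{FC}_t}{\mathrm{activity}_{dt}\,(\mathrm{nM})}
  \cdot Z'_{tj} \cdot 100 \cdot W_j
  \;=\; 100 \sum_t \frac{\log_2\mathrm{FC}_t}{\mathrm{activity}_{dt}}
  \mathrm{TIHS}_t,$$

and the signed **drug sensitivity score** is $\mathrm{Total}_d$ times an
effect multiplier ($+1$ inhibitory/suppressive, $-1$ agonist/activator,
keyword-matched case-insensitively with "antagonist" checked before
"agonist"; indeterminate mechanisms are excluded rather than defaulted,
because a wrong sign is worse than a missing drug). Both algebraic forms
are computed and asserted equal at run time, which guards the weight/shift
bookkeeping. Multiple activity measurements per (drug, target) pair are
aggregated by median nM before scoring (configurable to geometric mean or
minimum); the median is robust to assay outliers.

Candidates then face three tiers: (1) positive score and rank within the
top 10% of all evaluated agents; (2) at least 2 matched topological
targets, deprioritizing single-target agents prone to bypass resistance;
(3) feasibility — every matched target detectably expressed (when an
expression table is supplied) and mean matched-target potency within the
drug's clinically achievable plasma concentration $C_{max}$ (when a
$C_{max}$ table is supplied). The mean matched-target potency is a proxy
for a measured IC50 and is labelled as such; drugs absent from the
$C_{max}$ table pass tier 3 with a warning rather than silently
disappearing. No rows are dropped — all flags are retained.

### Validation statistics

* paired comparison of two scoring schemes: **exact one-sided McNemar** on
  the discordant pairs, $p = \sum_{k \ge n_{10}} \binom{n}{k} 2^{-n}$ with
  $n = n_{10}+n_{01}$. The exact (rather than chi-squared) form is used
  because with $n_{01}=0$ the p-value is exactly $0.5^{n_{10}}$;
* directional accuracy against chance: one-sided exact binomial;
* uncertainty: percentile bootstrap (10,000 iterations by default);
* rank-based validation: the direct p-value of a drug is
  $\mathrm{rank}/N$; the permutation version compares it to uniform draws
  with the add-one estimator $(1+b)/(m+1)$, which cannot return zero and
  keeps the test valid (super-uniform under the null — verified by a
  calibration test at 1000 replicates);
* top-decile enrichment: exact binomial tail, or the equivalent
  permutation simulation;
* weight distributions: chi-squared goodness-of-fit against the uniform
  1/5 vector (df = 4) and contingency homogeneity across datasets. These
  act on proportions and therefore need a pseudo-count basis; the basis is
  a convention (default: the network node count), it scales the statistic
  linearly, and it is always reported alongside the result. Published
  chi-squared magnitudes for weight homogeneity are not comparable without
  knowing the original count basis, so this operation is property-tested
  (zero statistic on identical rows, correct df, closed-form 2x2 case)
  rather than checked against any published magnitude.

### Resistance-shift heterogeneity

`build_shift_matrix()` intersects the gene sets of several models (no
imputation) into a genes x models $\log_2$FC matrix. Models are compared by
PCA on centered, unscaled model vectors (`prcomp` convention), pairwise
Pearson correlation, and complete-linkage clustering on $1-r$ distance.
Gene-level bootstrap (500 iterations by default) resamples genes with
replacement and recomputes the embedding; each iteration's PCs are
sign-aligned to the reference embedding (sign chosen to maximize agreement
with the reference coordinates), since otherwise arbitrary per-iteration
eigenvector sign flips would scramble the coordinate clouds into artificial
bimodality.

## The synthetic generator

`synthetic_config()` defines the study conditions used by the recovery
tests: 300 genes, 8 planted hubs, 6 planted sensitive (inhibitor) drugs, 6
planted resistant (agonist) drugs and 60 decoys. Hubs are planted by extra
attachment (each hub is wired to 30% of all nodes on top of an
Erdős–Rényi background at edge probability 0.03), not by preferential
attachment, so hub identity is a controlled, known quantity. Edge
confidences are uniform on $(0.4, 0.999)$, making the 0.7 high-confidence
cut genuinely selective. Planted hubs are upregulated
($\log_2\mathrm{FC} = +2$, padj $< 0.01$) so that a potent inhibitor's
sensitivity score is positive.

Background genes are a two-component mixture controlled by `de_fraction`
(default 0.65): *null* genes have $\log_2\mathrm{FC} \sim N(0, 0.3)$ and
padj $\sim U(0,1)$; *perturbed* genes have $\log_2\mathrm{FC} \sim
N(0, 1.5)$ and padj $\sim U(0, 0.02)$. The mixture emulates the
effect-size/p-value coupling of real differential-expression output — in
real DE tables large fold changes and small adjusted p-values co-occur, and
resistance cohorts yield thousands of DEGs. A pure null background
(`de_fraction = 0`) makes the DEG-induced network degenerate (a pure null
can contribute at most $5\% \times P(|\mathrm{FC}|\ge 1)$ of genes, so the
network would collapse to the planted hubs plus a handful of nodes, and a
"top decile" of such a network cannot even contain 8 hubs); the mixture
yields networks of roughly 90–100 nodes at the default configuration, which
is the regime the scoring is meant for. The closed-form background pass
rate is still tested at `de_fraction = 0`, where the generator reduces
exactly to the pure-null form.

Planted drug potencies are 10–300 nM versus 500–5000 nM for decoys —
nanomolar-scale potency against hubs versus weaker potency against
non-hubs, the contrast the tier filters are designed to exploit.

What the generator does **not** emulate: cohort-specific expression
distributions, correlated DEG structure (co-regulation), scale-free degree
distributions beyond the planted hubs, realistic ChEMBL potency spectra,
or assay noise in activity values. Passing recovery tests therefore shows
that the pipeline recovers planted signal under controlled conditions, not
that it reproduces any particular cohort's biology.

```{r recovery, message = FALSE, warning = FALSE}
sim <- simulate_study(synthetic_config(seed = 42))
degs <- filter(sim$degs, abs(log2fc) >= 1, padj < 0.05)
res <- run_tihs(degs, sim$edges, sim$drug_targets, seed = 42,
                epc_realizations = 250)
glance(res)
# do the planted hubs top the hubness ranking?
head(res$hubness$gene, 8)
sim$truth$hub_genes
```

## Numerical choices

* **Population (n) standard deviation** for Z-scores, not sample (n-1): a
  documented convention; it cancels in rankings and in the weight shares.
* **Eigenvector centrality** is computed by power iteration (tolerance
  `1e-10`, at most 10,000 iterations, uniform start vector) on $A + I$.
  The unit diagonal shift leaves eigenvectors unchanged but makes the
  dominant eigenvalue strictly largest in magnitude even on bipartite
  graphs, where plain power iteration oscillates with period 2.
* **EPC deletion rule** is strict (`confidence < t` deletes), so a
  confidence of exactly 1 is never deleted — high-confidence edges are
  immortal under percolation. EPC defaults to 1000 realizations (the
  CytoHubba convention) and requires a seed for reproducibility. The
  normalization by network size and averaging over realizations is a fixed
  convention of this package; by the Z-score invariance above it has no
  effect on TIHS.
* **MCC** guards against factorial blow-up with a configurable cap on the
  maximal clique count (default $10^6$), erroring rather than hanging.
* **Ties** are always broken deterministically: hubness ties by gene name;
  drug-score ties by matched-target count then drug name; equal-sized
  components by the alphabetically first member; PCA and bootstrap signs
  as described above.
* **Degenerate inputs**: constant centrality columns get all-zero Z
  (shifted to the 0.001 floor) and zero weight; single-node matrices,
  empty networks, zero discordant pairs and zero-variance weight vectors
  raise explicit errors rather than NaNs.
* **Duplicate records**: DEG tables keep the row with maximum
  $|\log_2\mathrm{FC}|$ per gene (ties: smaller padj, then first
  occurrence) — the strongest resistance signal; reciprocal/duplicate
  edges merge keeping the maximum confidence; gene symbols are upper-cased
  everywhere before matching.

## Problem sizes used by the test suite

The suite verifies the centralities against exhaustive brute-force oracles
on all labeled connected graphs up to 5 nodes and random connected graphs
at 6–7 nodes (full enumeration of labeled 7-node graphs — $2^{21}$ — adds
nothing over a dense random sample at these sizes); EPC against closed
forms at 10,000 realizations; and end-to-end recovery over 20 synthetic
seeds at the default configuration with 250 EPC realizations per network,
a realization count at which the EPC column is already rank-stable for
networks of ~100 nodes. All randomized checks fix their seeds.

## Known limitations

* TIHS is static and mechanism-agnostic: it nominates structurally central
  nodes but does not model feedback, pathway cross-talk or network
  rewiring, and a high score is not a causal claim.
* The drug score divides by potency in nM, so it is sensitive to the
  quality and unit hygiene of the activity table; only nM/uM/M inputs are
  accepted and nonpositive activities are dropped loudly.
* Weight derivation from variance shares is one of several defensible
  conventions; both implemented modes are labelled in every output, and
  per-dataset weight values should not be expected to transfer across
  conventions.
* The tier-3 feasibility check uses mean matched-target potency as an IC50
  proxy when no measured cellular IC50 is available; it is labelled as a
  proxy and is no substitute for dose–response data.
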