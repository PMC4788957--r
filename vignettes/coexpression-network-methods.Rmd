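---
title: "Methods: building and interrogating gene co-expression networks"
author: "coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and interrogating gene co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

# The model

coexnet builds *hard-threshold* gene co-expression networks. Given a genes
x samples matrix of FPKM-like abundances, the co-expression level of two
genes is the absolute Pearson correlation |r| of their expression profiles
across samples, computed by default on log2(FPKM + 1) (the log stabilises
the heavy right tail of FPKM values; raw-scale correlation is available
via `log2Transform = FALSE`). For a cut-off t, the network G_t contains an
undirected edge for every pair with |r| strictly greater than t, weighted
by |r| and signed by the sign of r; genes left without any edge are not
part of the node set. Edge sets are therefore nested along t, which many
tests exploit.

## Threshold selection

The cut-off is chosen as a compromise between two criteria:

* **scale-free fit.** For each candidate t the degree distribution
  P(k) — the fraction of nodes with degree exactly k, raw frequencies at
  the observed k with no log-binning — is regressed in log10-log10 space,
  and the R-squared of the ordinary least-squares fit measures how close
  G_t is to the power law P(k) ~ k^-lambda. The estimated exponent is
  lambda = -slope. At least three distinct degrees are required; fits on
  fewer are reported as undefined rather than extrapolated.
* **density.** The mean degree traces how much of the correlation
  structure survives the cut. The scan reports mean degree over *all*
  input genes (fixed denominator): this quantity is guaranteed to be
  non-increasing in t, whereas the within-network ratio 2E/N can
  fluctuate as isolated genes drop out of N. The per-threshold node count
  still tracks the thresholded network itself.

`selectThreshold()` returns the t maximizing R-squared among non-empty
networks, breaking ties toward the smaller t (the denser network). On
real compendia the fit typically rises with t and then degrades once the
cut is so strict that the network disintegrates; the selected maximum
sits before that collapse. On sharply planted synthetic blocks (below)
the fit maximum can sit at high t where only the strongest pairs remain —
the planted-recovery checks are therefore run at explicit thresholds,
and the scan checks test monotonicity, nestedness and the argmax rule
rather than a particular selected value.

## Differential-expression prefilter

When a per-comparison adjusted-p-value table is supplied, a gene enters
the correlation step only if its smallest adjusted p across comparisons
is strictly below alpha (default 0.05). Genes never tested are dropped.
This mirrors the common practice of networking only genes that move in at
least one condition; the variance estimation behind those p-values is
upstream of this package.

# Topology and significance

`summarizeTopology()` reports node/edge counts, component sizes, the
percentage of genes in the major component (one decimal), the mean local
clustering coefficient, the mean shortest-path length, the true diameter
and the scale-free fit.

Conventions worth stating because the literature is not uniform:

* the *local clustering coefficient* of a gene is triangles through it
  divided by deg(deg-1)/2, with coefficient 0 for degree < 2 (this
  affects the network average and is asserted explicitly in tests);
* the *average path length* is the mean BFS distance over unordered
  pairs **within the largest component**. Co-expression papers sometimes
  call this quantity the "network diameter"; `networkDiameter()` returns
  the true maximum eccentricity separately;
* *HITS scores*: for an undirected graph the HITS hub and authority
  vectors coincide with the principal eigenvector of the adjacency
  matrix. The package computes it by power iteration on (A + I) with L2
  normalization — the unit diagonal shift leaves eigenvectors unchanged
  but guarantees convergence on bipartite graphs (a star graph makes the
  plain iteration x <- Ax oscillate with period 2 forever). Scores are
  rescaled so the maximum is 1; genes in minor components receive scores
  near zero because the iteration converges on the component with the
  largest spectral radius. Convergence is declared when the L2 change
  per step falls below `tol` (default 1e-10) and failure to converge
  within `maxIter` raises an error reporting the residual — on graphs
  whose two largest components have nearly equal spectral radii the
  iteration is legitimately slow and a larger `maxIter` is the remedy.

Significance of a topology statistic is judged against seeded null
ensembles with matched node and edge counts: Erdos-Renyi G(n, m) graphs
(exactly m edges, drawn uniformly) or Barabasi-Albert
preferential-attachment graphs with m = max(1, round(E/N)). The empirical
p-value is (1 + ties-or-better) / (replicates + 1): ties count as
beating, the smallest attainable value is 1/(R+1), and an observation
equal to the single null sample yields p = 1. The package default of
10^4 replicates follows common practice; tests and the acceptance script
use a few hundred, which changes resolution but not the estimator.

# Clustering and model selection

Genes are clustered on the dissimilarity d = 1 - |r| (anticorrelated
genes are *similar*: they move together, in opposite directions). Two
algorithms are offered, matching the most widely used pair:

* `clusterPAM()`: Kaufman-Rousseeuw partition around medoids, the exact
  BUILD + SWAP algorithm via the cluster package. It is deterministic
  given the dissimilarity; note SWAP reaches a *local* optimum of the
  total-dissimilarity objective, which coincides with the global optimum
  on well-separated data but need not in general.
* `clusterHclustAverage()`: agglomerative average-linkage (UPGMA)
  clustering cut into k groups. Average linkage is the conventional
  default where the linkage is not otherwise specified.

Quality is scored by the silhouette: s(i) = (b - a)/max(a, b) with a the
mean within-cluster dissimilarity of gene i (excluding itself) and b the
smallest mean dissimilarity to another cluster; members of singleton
clusters score 0, as do genes with a = b = 0. `selectClustering()`
evaluates every (algorithm, k) pair — default k = 4..20 — and returns the
candidate with the highest mean silhouette, ties broken toward smaller k
and PAM before hierarchical clustering. Clustering is applied to network
member genes, not to every input gene: the network is the object under
study, and the cut-off has already removed genes with no strong partner.
PAM's SWAP phase costs O(k(n-k)^2) per pass, acceptable into the low
tens of thousands of genes; subsample beyond that.

# Enrichment

Over-representation is always the one-sided Fisher's exact test: the
upper hypergeometric tail P(X >= a) for the 2x2 table of study/background
by with/without property, evaluated through the log-space tail of
`phyper`. Unannotated background genes are kept as property-absent — the
background is the entire gene universe, not the annotated subset.

Because sparsely annotated genomes force annotation transfer, term calls
combine two independent routes (ortholog-transferred terms and protein
domain/family terms): a term is significant when **both** routes find it
at p < 0.05, or when a **single** route finds it at p < 1e-6. The strict
single-source cutoff is the published convention this rule follows; the
per-source 0.05 for the dual branch is this package's reading, since only
the strict branch is stated numerically in the sources the rule derives
from. No multiple-testing correction is applied to GO p-values by
default (the topGO-style convention); `bhAdjust()` is provided for users
who want it.

Marked-set enrichment across clusters (e.g. transcription factors per
cluster) uses the same test on in/out-of-cluster counts.

# Perturbation validation

If the network predicts regulation, perturbing a gene should shift the
expression of its neighbourhood. `neighborhoodAtDistance()` collects all
genes within BFS distance d (focal gene excluded for d >= 1);
neighbourhoods are nested in d. `foldChangeShiftTest()` compares member
fold changes against the rest of the network with a one-sided
Mann-Whitney U test — chosen for robustness to the skew of FPKM-derived
fold-change ratios; Welch's t on log2 fold changes is available behind
`method = "t"`. Exact enumeration is used when both groups have at most
12 untied values, the normal approximation with tie correction
otherwise; if every fold change is one identical value the variance of U
is zero and the test reports p = 1 (no evidence of a shift). "Increased"
means ratio > 1 (log2 > 0), and the strongly-responsive cut-off is
inclusive: fold change >= cutoff (default 4), with down-responders at
<= 1/cutoff. Enrichment of responders inside a neighbourhood or cluster
is again the one-sided Fisher test.

# The synthetic-data generator

`simulateBlockExpression()` emulates a multi-condition compendium with
planted ground truth: each block has a latent standard-Gaussian sample
profile, members are alpha * latent + noise (alpha uniform in 0.8–1.2,
sign-flipped for an `antiFraction` subset), and background genes are
independent noise. Latent profiles are centred and mutually
orthogonalized so between-block gene correlations are purely
noise-driven; without this, one chance correlation between two latent
draws would propagate to *every* between-block gene pair and the planted
separation would be at the mercy of the seed. The noise sd defaults to
sqrt(1/withinCorr - 1), which makes the expected within-block correlation
equal `withinCorr` on the latent scale. Latent values are exponentiated
(base 2, around a typical log2-FPKM level of 5) to lognormal FPKM-like
marginals floored at 0.01, so the log2(v + 1) transform used before
correlation recovers the planted structure. Each call consumes one
seeded stream and restores the caller's RNG state; identical designs and
seeds give bit-identical matrices.

What the generator does *not* emulate: read-count noise and library-size
effects, correlated blocks of unequal strength, hub-and-spoke wiring
within modules, or any specific biology. Consequently, passing the
planted-recovery tests shows the machinery is correct — thresholding
separates the planted modules, silhouette selection finds the planted k,
the shift test detects a planted neighbourhood effect — not that the
pipeline would reproduce any particular real network's headline numbers,
which depend on data this package deliberately does not ship.

`fixtureGraph()` supplies the deterministic graphs (star, triangle, path,
complete, planted partition) whose statistics are hand-checkable and
anchor the oracle tests.

# Numerical choices and degenerate inputs

* Correlations are symmetrized, clamped to [-1, 1], with diagonal set to
  exactly 1; zero-variance genes (correlation undefined) are excluded
  and reported, not imputed. Expression input with missing cells is
  rejected.
* Strict inequalities: |r| > t for edges, adjusted p < alpha for the DE
  filter. Boundary cases (|r| = t, p = alpha) are excluded by tests.
* GML serialization writes edge weights with 6 decimals; fixture and
  pipeline networks round-trip exactly, arbitrary correlation weights to
  1e-6.
* Ties: threshold selection prefers smaller t; hub ranking prefers
  higher HITS score then lexicographic gene id; model selection prefers
  smaller k then PAM; component ordering prefers larger size then
  smallest member id.
* Empty studies, empty marked sets, all-annotated backgrounds, edgeless
  graphs and single-cluster labelings all return the documented
  degenerate values (empty tables, p = 1, errors) rather than NA
  propagation.

# Problem sizes

The test-suite and acceptance-script study conditions are fixed at a few
hundred genes and a few dozen samples (5 blocks x 40 genes + 50
background x 24 samples for the acceptance run; null ensembles of a few
hundred replicates; Barabasi-Albert checks at n = 2000). These sizes were
chosen so every quantity is recomputed from scratch in seconds while
leaving all algorithms in their asymptotic regime; nothing in the
implementation is specialised to them.

# Known limitations

* Hard thresholding only: no soft-threshold (weighted) adjacency and no
  topological-overlap measures.
* Plain Fisher ("classic") scoring for GO terms: no GO-graph-aware
  elimination or weighting.
* PAM is the exact algorithm, not a sampling variant; very large
  networks need subsampling.
* The scale-free R-squared uses unbinned frequencies; heavily binned or
  cumulative-distribution fits would give different absolute values.
* Correlation is Pearson on log2(FPKM + 1); rank-based alternatives are
  not implemented.
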