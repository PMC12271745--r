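---
title: "Methods: significance-called chromatin networks and their integration with co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: significance-called chromatin networks and their integration with co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromanet)
```

## Overview

chromanet compares the 3D genome organisation of two conditions (e.g. tumor
vs normal tissue) through per-chromosome networks. Three layers of analysis
build on each other:

1. **Significance calling.** Raw intrachromosomal Hi-C contact counts are
   tested against a Fisher noncentral hypergeometric (NCHG) null whose odds
   ratio encodes the expected distance decay, and edges are retained by
   Benjamini–Hochberg FDR. The retained contacts define an undirected,
   unweighted network of genomic bins per chromosome.
2. **Differential network statistics.** Condition-paired networks are
   compared by Jaccard similarity (nodes, edges, edge classes), degree and
   Z-weighted degree, a per-node neighbourhood dissimilarity index (DI)
   thresholded by kneedle elbow detection, and contact-level log2 fold-change
   maps and decay curves on ICE-balanced matrices.
3. **Integration with expression.** Per-chromosome gene co-expression
   networks are inferred by bootstrap-consensus mutual information, joined to
   the chromatin layer through gene-to-bin interlayer edges, partitioned by
   weighted Louvain, and summarised as community-membership change
   percentages and structure–expression change quadrants.

Every stage is validated against a synthetic-data generator that plants
known peaks, biases, modules and changes, so each statistic has a recovery
oracle.

## The significance model

For a pair of bins $(i, j)$ with observed count $n_{ij}$, chromosome total
$n$, and bin marginals $n_i$, $n_j$, the null is Fisher's noncentral
hypergeometric distribution with population $2n$, $n_i$ success states,
$n_j$ draws and odds ratio $\omega_{ij}$:

$$P(n_{ij}) \propto \binom{n_i}{n_{ij}} \binom{2n - n_i}{n_j - n_{ij}}
\,\omega_{ij}^{\,n_{ij}},$$

normalized over the support
$[\max(0, n_j - (2n - n_i)),\ \min(n_i, n_j)]$. The p-value is the
upper-tail survival probability $P(X \ge n_{ij})$; all mass computations run
in log space with log-sum-exp normalization (a compiled kernel handles the
per-chromosome bulk; support enumeration refuses more than $10^6$ states).

### The distance-decay null

The expected per-pair contact probability $f(d)$ is estimated by pooling all
candidate pairs (zero-count pairs included — omitting them would bias the
far-distance expectation upward) into consecutive metabins of 200
distance-ordered pairs, taking each metabin's mean distance and mean
probability, enforcing monotone non-increase by isotonic regression, and
interpolating the adjusted knots with a monotone (Hyman-filtered) cubic
spline, clamped at the boundary knots. The metabin size is configurable; 200
pairs per metabin is the default.

### The odds ratio, and why it is not the naive one

Three facts shape the construction of $\omega_{ij}$, each verified on the
generator:

- **Technical biases cancel.** The marginals $n_i$ conditioning the null
  already carry each bin's visibility bias, so multiplying the biases into
  $\omega$ double-counts them; on simulated maps with lognormal biases this
  inflates low-visibility pairs to ~90% false calls. Biases therefore enter
  only the admissibility filter (default bounds $[0.5, 2]$), not the odds
  ratio.
- **Position does not cancel.** On a finite chromosome, bins near the ends
  have fewer close neighbours, hence smaller marginals for the same
  visibility — a *positional* factor $s_i = \sum_j f(d_{ij})$ that the
  distance-only odds ratio misses. Without the correction, every
  near-telomere adjacent pair is called (p-values down to $10^{-103}$).
- **The linear regime ends near the diagonal.** At one-bin separation the
  expected count is ~9% of the marginals, where the NCHG mean falls visibly
  below $n_i n_j \omega / 2n$. We therefore *mean-match*: the target
  expectation $\mu_{ij} = (n_i n_j / 2n)\,\cdot 2 f(d)/ (s_i s_j p̄)$-scaled
  form is converted to the odds ratio of the expected 2×2 table,
  $$\omega_{ij} = \frac{\mu (2n - n_i - n_j + \mu)}{(n_i - \mu)(n_j - \mu)},$$
  which makes the null mean equal the decay expectation at every distance
  and position.

With all three in place, a pure-decay simulation yields a p ≤ 0.05 fraction
of 0.036–0.050 (the mild conservatism is the discreteness of the count
support) and BH at q ≤ 0.05 calls essentially nothing on a null map, while
recovering ≥ 99% of 8-fold planted peaks with a false-call fraction at the
FDR level.

The exported `expected_odds()` keeps the simple interpretable form — odds of
the bias-adjusted decay probability against the odds of the global mean —
and is what the caller uses internally with positional correction factors in
the bias slots.

Filters run before testing, in a fixed order with a per-filter ledger:
blacklist overlap (any overlap of a bin with an interval disqualifies the
bin), centromere overlap, self-interactions (the diagonal), and bias bounds.
Candidate pairs for testing are the observed (count ≥ 1) pairs; zero-count
pairs have p = 1 by construction and would only dilute the BH family.
BH is applied per chromosome — each chromosome's candidate set is one
multiple-testing family, matching the per-chromosome network construction.

## Network construction and comparison

Edges with q-value strictly below the network cut (default $10^{-3}$; the
FDR retention level, default 0.05, bounds it above) form the chromatin
network. Nodes carry their bin coordinates and a three-way type: `C` if the
bin contains a coding-gene TSS (coding precedence for mixed bins), `R` for
ncRNA-only bins, `N` otherwise; edge types are the unordered endpoint-type
pairs written in C, R, N order. Isolated bins are excluded by default so
node-level comparisons address interaction-participating regions; a
`keep_isolated` flag restores them.

Z-scores standardize each chromosome's retained edge counts by that
chromosome's own mean and population standard deviation; the Z-weighted
degree of a node is the sum of the absolute Z-scores of its incident edges.

The dissimilarity index of a node present in both conditions is one minus
the Jaccard similarity of its neighbour sets; the ranked DI profile is
thresholded at the kneedle elbow — the argmax of the normalized difference
curve $x - y$ on the rank-normalized profile, the orientation appropriate
for convex increasing curves. No smoothing is applied: ranked profiles are
monotone, so the exact argmax is deterministic, with ties resolved to the
smallest index. A pure linear ramp has no elbow and raises an error rather
than fabricating one.

Two empty sets compare as Jaccard 1 (identical) with a logged message —
relevant only for degenerate stratified comparisons.

## Co-expression layer

Counts are filtered by the low-expression rule (≤ 10 reads in > 80% of
samples, both conditions pooled) and scaled by median-of-ratios size
factors (geometric-mean reference over all-positive genes; verified against
the DESeq2 implementation in the test suite).

Mutual information between two genes is a plug-in estimate on a
$B \times B$ equal-frequency grid of rank-transformed values,
$B = \lfloor\sqrt{n/5}\rfloor$ (minimum 2), minus the Miller–Madow
first-order bias $(B-1)^2/2n$, clamped at zero. Rank transformation makes
the estimate invariant under monotone transforms (so the choice of
normalized vs raw input is nearly moot) and symmetric. On bivariate
Gaussian data at $\rho = 0.9$ the estimate lands within a few percent of the
closed form $-\tfrac12\ln(1-\rho^2)$; under independence it averages below
0.02 nats.

The MI significance threshold at tail probability $p$ (default $10^{-8}$)
is extrapolated from a permutation null: MI values for random gene pairs
with one member's samples permuted, an exponential tail fitted to the upper
5% by a linear fit of log empirical survival, and the threshold read off at
the target probability. This reaches tail probabilities far beyond what the
$10^4$ null draws could reach empirically. The threshold is estimated once
globally (per-chromosome estimation is possible by calling it per subset).

The consensus network draws B = 100 bootstrap resamples of samples; each
resample contributes edges for all intra-chromosomal gene pairs at or above
the MI threshold. Pair support $k$ out of B is tested against a Poisson null
with rate $\lambda$ equal to the mean support over all candidate pairs — the
simplest rate consistent with "a Poisson distribution" — with Bonferroni
correction over the candidate pairs at family level 0.05. Edge MI is the
median across supporting bootstraps. All-versus-all pairs are tested because
the regulator list is the expressed gene set itself.

## Multilayer integration

Genes map to the bin containing their TSS (0-based, half-open: a TSS at
exactly 40 kb belongs to bin 1). The unified graph namespaces node ids by
layer, connects each mapped gene to its bin with an interlayer edge of
weight 1, weighs chromatin edges by |Z| (count and unweighted schemes are
options) and MI edges by MI. Louvain community detection runs on the
weighted unified graph with a fixed seed and stated resolution; identical
seeds give identical partitions.

Louvain labels are arbitrary, so membership change between two partitions is
computed after greedy maximal-overlap label alignment (descending
contingency overlap, each community used at most once, ties to smallest
labels, unmatched communities fresh-labelled). This makes the change
percentage exactly invariant to relabelling — a bare label comparison is
not — and is computed overall and restricted to each layer.

The structure–expression table relates, per eligible gene pair, the Hi-C
count between the genes' bins to their MI, per condition and as log2 fold
changes (pseudocounts 1 for counts, 0.01 for MI). A pair absent from one
condition's MI network is threshold-censored to MI 0 there; pairs sharing a
bin are excluded (no self-distance contact value); eligibility requires
presence in at least one condition so gains and losses are representable.
Quadrants (both-up, both-down, hic-up-mi-down, hic-down-mi-up) are assigned
when both absolute fold changes exceed their cutoffs (defaults 1 and 0.5),
else `ns`.

## The synthetic generator

`simulate_hic_pair()` draws a multinomial allocation of the total contacts
over pairs with probability $\propto d^{-\alpha} b_i b_j$, times the
enrichment $\phi$ on planted peak pairs; biases are lognormal, clipped to
[0.5, 2]. The tumor map loses a stated fraction of total contacts, flattens
pair probabilities beyond the truncation distance to the decay floor (the
value at the chromosome's maximum distance), and rewires a fraction of peaks
to new pairs. Peaks are placed uniformly among pairs up to 5 Mb by default —
the genomic scale of cohesin loops and enhancer–promoter contacts, and the
scale at which an 8-fold enrichment over the local expectation is
statistically detectable at desk-scale sequencing depth; `peak_max_distance
= NULL` spreads them over the whole chromosome (used by the long-range-loss
scenario, where normal-only distal peaks are the point).

`simulate_expression_pair()` uses a latent factor per module (loading
$\sqrt\rho$, so latent within-module correlation is $\rho$) and a
negative-binomial observation layer with per-sample library factors; module
genes occupy contiguous bins so co-expression is spatially aligned with the
chromatin layer. The tumor condition reassigns a fraction of module genes to
other modules. `simulate_community_pair()` builds paired two-layer
clique-module graphs with a planted fraction of moved nodes (optionally in
one layer only), and `simulate_coupled_pair()` plants per-pair change
quadrants with a stated concordance (or fully decoupled directions).

What the generator does *not* emulate: TAD/compartment block structure,
replicate-level variability, copy-number effects, trans contacts, and
condition-specific library composition shifts. Passing the recovery tests
therefore shows the statistics do what they claim under a clean power-law
null with planted structure — not that real tissue Hi-C meets those
assumptions.

### Default study conditions

One synthetic chromosome of 500 bins × 40 kb (20 Mb), $10^6$ contacts,
decay exponent 1, 100 peaks at 8-fold enrichment, bias sd 0.2; tumor: 30%
contact loss, 5 Mb truncation, 30% peak rewiring. Expression: 200 genes, 60
normal + 40 tumor samples, 8 modules of 10 genes at $\rho = 0.8$, NB
dispersion 0.05, 30% module rewiring. These run in minutes on one CPU; the
end-to-end determinism checks use a reduced shape (150 bins, $2\times10^5$
contacts, 20 bootstraps) since the property being checked does not depend on
scale.

## Numerical and degenerate-input policy

- NCHG support wider than $10^6$ states, invalid parameters, or p-values
  outside the support raise domain errors; survival probabilities are
  floored at the smallest normal double (a discrete survival probability is
  never exactly zero, and `fdr_level = 0` must select nothing).
- ICE masks zero-marginal bins, reports iterations and the final
  coefficient of variation, errors if the CV tolerance is not met within
  `max_iter`, and normalizes biases to mean 1 (the row-sum equality is
  invariant to that rescaling). Balancing a balanced map returns unit
  biases.
- Degenerate inputs (all-equal counts for Z-scores, all-equal DI values for
  kneedle, single-gene matrices, empty partitions) raise classed errors
  rather than returning fabricated values; the pipeline converts a
  degenerate structure–expression stage into an absent table.
- All randomness flows through explicit seeds; the pipeline writes a
  manifest with every parameter and seed, and re-running with the same seed
  reproduces the artifacts byte for byte.

## Known limitations

- The positional-visibility and mean-matching corrections assume the decay
  model is estimated on the same filtered candidate set that is tested;
  supplying an external decay model from a different mask weakens the
  calibration guarantee.
- The NCHG conditions on marginals; focal amplifications that inflate a
  bin's marginal depress its other pairs' significance (a conservative
  failure mode).
- The exponential-tail extrapolation of the MI null to $10^{-8}$ leans on
  the tail being exponential beyond the simulated range; diagnostics (fit
  slope, empirical 95th percentile) are attached to the returned threshold.
- Louvain is seed-stable but not globally optimal; community-change
  percentages inherit its resolution limit. The label-alignment step removes
  permutation artefacts but cannot resolve genuine community splits/merges
  into a single "changed" notion — split halves beyond the best-overlap
  match count as changed.
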