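---
title: "Screening protein pairs for coevolving residues: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein pairs for coevolving residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevscreen)
```

## The problem

When two proteins interact, substitutions at an interface position of one
are often compensated by substitutions in the other, so the *placement* of
substitutions on the species phylogeny becomes correlated between specific
residue positions of the two proteins. `coevscreen` turns a set of
per-protein orthologue alignments into a residue-level screen for this
signal: every unordered protein pair is restricted to the species both
proteins were found in, every informative column pair is scored, and the
surviving hits are aggregated into per-pair statistics and a network.

## The variation vector and its correction for divergence time

For an alignment of $n$ shared species, a column $a$ is represented by a
vector over the $n(n-1)/2$ unordered sequence pairs $(i,j)$. The default
("binary") flavour is

$$v_a(i,j) = \frac{\mathbf{1}[x_{ai} \neq x_{aj}]}{\max(t_{ij},\,t_{\min})},$$

the indicator of an amino-acid transition between sequences $i$ and $j$,
normalized by their patristic divergence time $t_{ij}$. Dividing by $t$
up-weights transitions between closely related species, which carry the
most placement information; $t_{\min}$ (default $10^{-6}$
substitutions/site) only guards against division by a degenerate zero
branch. Coevolution between columns $a$ (protein A) and $b$ (protein B) is
the Pearson correlation of $v_a$ and $v_b$ over the sequence pairs usable
in both.

Two alternatives are provided. `variation = "blosum"` weights each
transition by its severity, $(s(x_i,x_i)+s(x_j,x_j))/2 - s(x_i,x_j)$ under
a BLOSUM log-odds matrix, before the time normalization: radical exchanges
count more than conservative ones. `variation = "classic"` is the textbook
correlated-variation score, the squared centered residual
$D_a(i,j) = (\hat\theta_a(i,j) - \bar{\hat\theta}_a)^2$ of the raw
time-normalized BLOSUM transition score $\hat\theta = s(x_i,x_j)/t_{ij}$
(this is also what the exported `site_variation()` computes).

Why is the indicator the default? The classic squared score is dominated by
structure every column shares: $1/t_{ij}$ spans two orders of magnitude
across sequence pairs, so the variation vectors of *any* two columns —
including fully conserved ones — are nearly proportional, and their
correlation is driven by the phylogeny rather than by coupled
substitutions. In our benchmark (independent proteins, 30 taxa, 200
columns) the median cross-column correlation of the classic score exceeds
0.99. The severity weighting removes the conserved-pair component but
still injects score-profile noise: two columns whose substitutions
co-occur on exactly the same branches can correlate weakly simply because
the residues exchanged score differently. The indicator measures exactly
what coupling produces — co-placement of substitutions — and recovered
every injected signal in our benchmarks that carried at least two
parsimony-visible substitutions, while the weighted flavours missed some.
The BLOSUM matrix retains its other roles (curation alignment scoring, the
simulator's substitution model, compatible-target selection, and the two
optional flavours).

## Which columns are scored

A column enters the scan only if

* at least `min_pair_fraction` (default 0.5) of its sequence pairs are
  usable — neither residue a gap or `X`, divergence time positive;
* it shows at least `min_subst` (default 2) substitutions on the protein's
  tree, counted as the column's Fitch parsimony score. A column with a
  single substitution event tells us only which branch it fell on; two
  such columns "coevolve" perfectly whenever their single events happen to
  share a branch, which at a few hundred columns per protein produces
  guaranteed spurious perfect correlations. Requiring two independent
  placements makes agreement informative;
* its variation vector is not constant (a constant vector has no
  correlation).

## Significance: matched column-pair null, bootstrap, bidirectional runs

The null distribution is built per protein pair from the data themselves:
`null_samples` (default 10,000) correlations of a random usable column of A
against a random usable column of B, keeping the natural sequence-pair
indexing. Under the no-coevolution hypothesis an observed site pair *is*
such a random draw, so permutation p-values
$p = (1 + \#\{\rho_{null} \ge \rho\})/(N+1)$ are calibrated by
construction and the $(1-\alpha)$ null quantile keeps the fraction of
threshold-exceeding column pairs at $\alpha$. A variant that additionally
permutes the pair indexing of the B column (`null_method = "permuted"`) is
kept for comparison; because it destroys the divergence-time structure the
two columns share, it is far from the distribution of the observed
statistic and should not be used for inference.

The correlation of indicator vectors is discrete — distinct column pairs
tie exactly — so reported p-values are conservative and lumpy.
`pvalue(..., randomized = TRUE)` provides the standard randomized
(tie-broken) p-value, exactly uniform under the null, used by the
calibration diagnostics; reported hit p-values are always the
non-randomized form.

A hit must clear the threshold *and* keep bootstrap support
$\ge$ `bootstrap_threshold` (default 0.6) under resampling of sequence
pairs (`bootstrap_reps` = 100), and must do both in two scans with
independent Monte-Carlo streams, the second with the roles of A and B
reversed; the reported p is the larger of the two. The reversed run exists
as a robustness protocol: the two runs share the observed correlations but
draw independent nulls and bootstrap streams, so borderline hits must
survive two independent randomizations.

## Multiple testing and pair-level aggregation

Hit p-values are Benjamini–Hochberg adjusted across the pooled residue
table by default (`fdr_scope = "pooled"`; per-pair families via
`"per_pair"`). Each protein pair is additionally tested for hit enrichment
with $\hat p = \sum n_{hits} / \sum n_{comparisons}$,
$E = n_{comparisons}\,\hat p$ and $\chi^2 = (n_{hits}-E)^2/E$ on 1 degree
of freedom — the simplest "more hits than expected" test using exactly the
recorded counts; the expectation is pooled across pairs rather than
per-protein, a choice this package fixes deliberately.

The final filters mirror the printed thresholds: residue rows survive iff
$p < 0.005$, both columns lie in good alignment blocks, and both gap
fractions are below 20% (all strict inequalities).

## Column quality

`column_quality()` is a deliberately reduced conserved-block labeller: a
column is *highly conserved* when its most frequent residue exceeds 85% of
rows, *conserved* when it exceeds half, *nonconserved* otherwise, and
forced nonconserved above 50% gaps; good blocks are maximal runs with no
stretch of more than 8 contiguous nonconserved columns, trimmed to
conserved ends, of length at least 10. These defaults mirror the common
defaults of conserved-block selection tools (minimum block 10, nonconserved
stretch 8, gaps "half"). Byte-level equivalence with any external block
tool is a non-goal; only the per-column good/poor label is consumed
downstream.

## Trees and curation

When no trees are supplied, each protein gets a neighbour-joining tree from
Poisson-corrected p-distances ($d = -\ln(1-p)$, gaps pairwise-deleted,
$p$ capped at 0.95 with a warning), rooted at the point minimizing tree
height (solved in closed form per edge; ties broken by edge index).
Negative NJ branch estimates are clamped to zero with the deficit moved to
the longest sibling. Plain Saitou–Nei NJ is used because it is exactly
testable against additive matrices; which distance a particular external
tree program would use is not knowable from the outside, so the distance is
configurable rather than guessed.

Orthologue curation replaces a similarity-search step with exact global
(Needleman–Wunsch, affine gaps, BLOSUM62, open 10 / extend 1) alignment of
every candidate to the reference sequence: candidate sets are small, so
exactness is affordable. Per species the best-scoring candidate is kept if
identity $\ge$ 35% and gaps $\le$ 25% (identity counted over aligned
positions by default; the denominator is a config switch). The divergence
screen scores each sequence by mean pairwise identity, rescaled by the
set maximum, and removes scores below `cutoff * median` (default cutoff
0.95). This is an acknowledged simplification: it is *not* an
alignment-confidence score, just a robust outlier screen with the same
stringency parameter.

## The benchmark generator

`simulate_dataset()` emulates the study conditions the screen targets: a
random bifurcating species tree (default 30 taxa; exponential branch
lengths, mean 0.05 substitutions/site), per-protein gap-free alignments
(default 200 columns) evolved under a reversible substitution model built
from BLOSUM62 exchangeabilities and background frequencies, with
per-site gamma rates (shape 1). Coevolving pairs are injected by
event-level simulation: site A evolves by Gillespie draws; with
probability `coupling` each substitution event at A forces a simultaneous
substitution at B on the same branch (target residue drawn among residues
scoring $\ge 0$ against A's new residue), while B's independent evolution
runs at $(1-\mathrm{coupling})$ times its rate — at coupling 1 the two
sites' substitution branch sets coincide exactly. Injected sites evolve at
twice the family mean rate by default (`coupled_rate = 2`): observable
coevolution requires variable sites, and under the default tree scale an
average-rate site carries $\sim$3 substitution events, leaving a
substantial chance of fewer than the two parsimony-visible changes the
usability rule demands. This is a property of the benchmark, set once from
that detectability argument.

What the generator does *not* emulate: indels arise only through the
optional `gap_fraction` block-gapping flag, there is no alignment error,
no rate variation across lineages, no among-protein tree discordance, and
the substitution model matches the engine's scoring matrix. Passing
benchmarks therefore demonstrate the statistical machinery under clean
conditions, not robustness to misalignment or model misspecification in
real orthologue data.

## Determinism and parallelism

Every Monte-Carlo stream derives its seed from the global seed, the pair
id, the run direction and the site coordinates (`derive_seed()`), so
results are bit-identical across repeated runs, worker counts and input
orderings; protein lists and pair ids are canonically sorted everywhere.
Benchmarks in the test suite use 2–10 proteins, 15–30 taxa and 60–200
columns, pooling about 35,000–45,000 site pairs for the calibration
checks; these sizes were chosen to exercise every code path at desk scale.

## Known limitations

* **Calibrated p-values produce dense raw networks.** With calibrated
  per-comparison p-values, a protein pair with $\sim 10^4$ scored column
  pairs retains about $0.5\%$ of them below a $p < 0.005$ filter — even
  between unrelated proteins. A negative-control panel therefore shows
  (by design of the arithmetic) at least one surviving residue hit in
  essentially every protein pair; sparse networks can only come from a
  *mis*calibrated (conservative) residue-level test or from pair-level
  aggregation. For screening decisions use the pair-level statistics —
  the $\chi^2$ enrichment test and `min_q` — rather than raw residue
  p-value filtering; the residue filter is kept because it reproduces the
  published protocol's thresholds.
* Site pairs whose columns carry fewer than two parsimony-visible
  substitutions are structurally undetectable and are excluded up front.
* The engine detects positive correlation of variation by default
  (`tail = "positive"`); anti-correlated variation is only reachable via
  `tail = "two_sided"`.
* Ancestral-state reconstruction is not used; the statistic is built from
  extant sequence pairs only, which needs no reconstruction step but
  cannot separate repeated substitutions on a single lineage.
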