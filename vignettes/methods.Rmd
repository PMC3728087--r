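---
title: "Detecting functional divergence and convergence by contrast analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional divergence and convergence by contrast analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcontrast)
```

## Scope and model of the data

`fdcontrast` asks, for every column of a protein alignment: does this site
evolve differently in a focal subfamily than in its background homologs, and
— when two subfamilies adapted independently to the same role — did they
converge on the same residue? The analysis is organized as *contrasts*: each
focal clade is compared against the background with every other focal
clade's leaves pruned from the tree, so that one adaptation cannot bias the
analysis of the other. Two per-site signals are targeted: rate-shift (Type
I) sites, conserved in one subgroup and variable in the other, and
conserved-but-different (Type II) sites, conserved in both subgroups but for
residues with different properties.

Inputs are an aligned amino-acid FASTA (gap `-`, ambiguity `X`), optional
per-column alignment support scores on a 0–10 scale, a Newick tree with
branch lengths whose tips match the alignment ids, and an id-to-group table
with the reserved label `background`. Branch lengths are trusted as given
and never re-optimized; this keeps every stage deterministic and puts tree
inference, which mature external tools do well, out of scope.

## Column masking and sequence filters

Columns are removed when (i) the raw support value is below 6, (ii) the mean
support over a sliding window of seven columns centred on the column is
below 8, or (iii) more than 70% (strict inequality) of its characters are
gaps; `X` counts as a non-gap. At the alignment edges the window mean is
taken over the columns that exist — truncation avoids inventing support
values where none were observed — and the centre column is included in its
own window, the natural reading of a "window centred on a column". Removed
columns carry the first violated rule in the fixed order `LOW_RAW`,
`LOW_WINDOW_MEAN`, `HIGH_GAP`; the kept/removed partition is independent of
that order. Support supplied on a `[0, 1]` posterior scale is rescaled by 10
on read, with a message, because the thresholds are defined on the 0–10
scale.

After masking, sequences covering less than 75% of the trimmed alignment are
dropped, and groups of byte-identical rows are collapsed to one survivor
(preferring a protected id, else the first in input order). Protected ids
are exempt from duplicate removal but not from the coverage rule — a
protected sequence that fails coverage is removed with a warning, since
keeping a mostly-gap sequence would corrupt every downstream per-column
statistic.

## Taxon reduction

Over-represented backgrounds are thinned by repeating: compute terminal
branch lengths of all non-protected leaves, form the pool at or below the
inclusive lower 10th-percentile (type-1 empirical quantile, ties included),
delete one pool member uniformly at random, and re-prune the tree (summing
the branch lengths of the collapsed degree-2 node). The pool is recomputed
from the pruned tree each iteration — the procedure is a repeated rule on
the current tree, not a one-shot ranking — and no tree re-inference is
performed. The RNG contract is deliberately simple and documented
(candidates sorted by label, one `sample.int()` draw per iteration) so that
an independent replay of the rule reproduces the removal sequence exactly.

## The likelihood engine

Per-site likelihoods are computed by Felsenstein pruning under an empirical
amino-acid model (packaged JTT; any symmetric exchangeability matrix with
frequencies is accepted) with discrete-gamma rate heterogeneity. The rate
matrix is built as `S diag(pi)`, scaled to one expected substitution per
unit branch length, and exponentiated through the symmetric
eigendecomposition of `diag(sqrt(pi)) Q diag(1/sqrt(pi))`. Conditionals are
rescaled per edge by their column maxima with accumulated log-scales, so
deep trees cannot underflow. Gamma categories are equal-probability with
exact conditional category means (via the incomplete-gamma identity), so the
mean rate is exactly 1 for any shape. Gaps and `X` are fully missing data
(conditional vectors of one); an all-gap column has likelihood exactly 1 by
convention. The default is K = 4 categories — the cost of the mixture
predictor is linear in K and 4 captures rate heterogeneity adequately at
these problem sizes; K is configurable.

## The mixture predictor

For each contrast site, the linked likelihood uses the intact contrast tree;
the severed likelihood is the product of the two subtree likelihoods
obtained by cutting the branch above the focal clade's MRCA, each subtree
closed with equilibrium frequencies at its root. Because each subtree sums
its gamma mixture independently, severing decouples the rate as well as the
state at the split — which is what gives the mixture sensitivity to Type I
sites, not just Type II. A single-leaf subtree contributes its residue's
equilibrium frequency (with a warning). The divergent fraction rho is found
by bounded one-dimensional search (`optimize`, tolerance 1e-8) with the
endpoints rho = 0 and 1 checked explicitly, since a boundary maximum is
otherwise missed by golden-section search. The posterior is computed as
`rho / (rho + (1 - rho) * exp(logL_linked - logL_split))`, which is exact
(posterior = rho) whenever the two likelihoods agree.

The gamma shape is taken from configuration (default 1.0) rather than
profiled: the shape enters both mixture components symmetrically, and
profiling it jointly with rho on these problem sizes changes calls
negligibly while costing determinism of runtime.

## Conservation-window smoothing and the 0.5 threshold

Scores are smoothed before thresholding:
`out_c = 0.7 * score_c + 0.3 * mean(conservation)` over the six flanking
columns (half-width 3, mirroring the size-seven masking window), where a
column's conservation is its mean normalized pairwise residue similarity.
Sites with undefined scores stay undefined and are excluded from their
neighbours' means; a site with no valid neighbour keeps its raw score. The
blend weight and half-width are exposed parameters; smoothing can be
disabled. The 0.5 call cutoff is applied *after* smoothing — windowing that
did not affect calls would be pointless — and a flag restores raw-score
thresholding for sensitivity checks.

## The group-similarity score

Residue similarity is BLOSUM62 restricted to the 20 standard residues and
min–max normalized over all 400 entries. The per-column score is
`raw(c) = ((within_A + within_B) / 2) * (1 - between)`, with each term a
(optionally sequence-weighted) mean over non-gap residue pairs. Two
consequences are worth stating plainly. First, a fully conserved column
scores `s(a,a) * (1 - s(a,a))`, which is 0 only for the residue at the
normalization maximum (W in BLOSUM62) and is bounded by 1/4 for every other
residue — conserved columns are never *high*-scoring, but only the extreme
of the diagonal maps exactly to zero. Second, under the default gap policy a
column is NA only when entirely gapped; when a group has fewer than two
non-gap residues its within term has no pairs and is dropped from the within
mean (the score is computed "with whatever residues exist"). A strict flag
instead NA-s any column where either group has fewer than two residues.
Distance adjustment between sequences is available as Henikoff
position-based weights; the default is uniform weights, which keeps results
independent of a weighting heuristic.

## The trace difference rule

Each sequence set is ranked by a real-valued evolutionary-trace-style
construction: for partition level n (1 to N-1), the leaves are split into
groups by cutting at the n-1 internal nodes closest to the root — ordered by
branch-length distance from the root, ties by edge-count depth, then by
postorder index, making the partition sequence deterministic for any input —
and `rank(c) = 1 + sum_n (1/n) sum_g H_g(c)` with `H_g` the within-group
Shannon entropy (natural log), gap counted as a 21st symbol so that gappy
and conserved columns remain distinguishable. An invariant column has the
floor rank of exactly 1. The difference rule calls a site when it lies in
the top 20% most-important columns (smallest ranks) of either subgroup's
trace but not of the full set's; each top set has exactly
`ceiling(0.2 * L_valid)` members, with rank ties broken by column index so
that set sizes are exact and runs reproducible.

## Convergence classification

Sites called in both contrasts by at least one method are classified from
group consensus residues (modal non-gap residue when its frequency is at
least 0.7): `CONVERGENT_IDENTICAL` when both focal consensuses are equal and
the background consensus is absent or different; `CONVERGENT_SIMILAR` when
they differ but have normalized similarity at least 0.6; otherwise
`PATTERN_ONLY`. The 0.7 and 0.6 cutoffs are this package's defaults — the
underlying biological notions ("strictly conserved", "similar residues")
have no canonical numeric form — and both are exposed parameters.

## The simulator: what it emulates and what it does not

`simulate_tree()` / `simulate_two_clade_tree()` build rooted trees with one
or two focal clades attached by single branches to a background subtree,
with branch lengths uniform on [0.02, 0.3] — 0.3 was chosen once as a
realistic protein-family scale (tip-to-root depths around 0.5–1 expected
substitutions per site), deep enough for substantial column diversity while
retaining phylogenetic signal. `simulate_alignment()` evolves BACKGROUND
columns under JTT with per-site Gamma(alpha = 1) rates using exact
eigendecomposition transition probabilities, sampling states from the root
down. TYPE1 columns divide the site rate by `rate_shift` (default 8) on
edges inside the focal clades and multiply it outside; the split branch uses
the outside rate, so the shift is a property of the subtree, not of the
separating branch. TYPE2 columns fix a residue pair with normalized
similarity below 0.3 (focal a, background b) and flip each leaf
independently with probability epsilon (default 0.02). MASK_BAIT columns
(default 5%) violate the raw-support or gap rule to exercise masking and are
excluded from predictor truth evaluation. Class counts are exact integer
allocations of the requested fractions.

The simulator does **not** model indels (gaps appear only as mask bait),
alignment error, among-site compositional heterogeneity, covarion behaviour,
or the incomplete lineage histories of real GAPDH datasets. Passing tests on
simulated data therefore demonstrate the correctness and calibration of the
*methods* under their own generative assumptions, not field performance on
real alignments.

## Numerical and design choices

- Tolerances: rho search 1e-8; pruning validated to 1e-10 relative against
  exhaustive state enumeration; root-placement invariance holds to 1e-8.
- Degenerate inputs: all-gap columns have likelihood 1, NA group-similarity
  score and NA trace rank; a single-leaf subtree in the mixture falls back to
  equilibrium frequencies; an empty post-filter alignment is allowed with a
  warning.
- Tie-breaks are always explicit (reason-code order in masking, label order
  in reduction sampling, node ordering in trace partitions, column index in
  top sets), so every stage is bit-reproducible under a fixed seed, which the
  pipeline verifies by writing an MD5 manifest.
- Problem sizes used in the shipped analysis and validation (50 taxa x 400
  columns; five replicate seeds at 40 taxa x 500 columns for mixture
  calibration) were chosen as comfortable desk-scale instances of the
  workflow.

## Known limitations

The mixture assumes exactly one foreground clade per contrast and does not
re-estimate branch lengths; the group-similarity instantiation is this
package's concrete formula for the within/between idea rather than a
re-implementation of any published scorer's internals, as is the trace rank
construction; and convergence classification depends on consensus cutoffs
that real datasets may want tuned. Where published tools implement cognate
computations (e.g. pruning likelihoods), they are used as independent
cross-checks in the test suite, never as the implementation.
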