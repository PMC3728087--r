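# fdcontrast

Contrast analysis of functional divergence and convergent evolution in
protein families.

## The problem

When a protein subfamily adapts to a new role — the motivating case is
plastid-targeted, NADPH-dependent GAPDH arising twice independently from
cytosolic, NAD-dependent ancestors — the adaptation leaves per-site traces in
a multiple sequence alignment: **Type I** (rate-shifting) sites that are
conserved in one subgroup but variable in the other, and **Type II**
("conserved-but-different") sites where each subgroup is conserved for a
different residue. Finding such sites, and asking whether two independently
adapted subgroups converged on the *same* residues, requires contrasting each
focal subgroup against the shared background with the other focal subgroup
pruned from the tree, so that neither adaptation biases the analysis of the
other.

`fdcontrast` implements that workflow for R users: alignment-confidence
column masking, short-terminal-branch taxon reduction, contrast-partition
construction, three per-site predictors of functional divergence, and
classification of sites shared between contrasts as convergent or not. A
built-in simulator with planted Type I/Type II sites makes every stage
testable without any sequence downloads.

## The three predictors

1. **Phylogenetic mixture (FunDi-style).** For each site $i$ of a contrast,
   the likelihood of the intact tree $L_{\text{linked},i}$ and of the two
   subtrees obtained by severing the branch separating the focal clade from
   the background, $L_{\text{split},i} = L_{A,i}\,L_{B,i}$, are computed by
   Felsenstein pruning under JTT with discrete-gamma rates. The fraction
   $\rho$ of divergent sites maximizes
   $\sum_i \log[(1-\rho)L_{\text{linked},i} + \rho L_{\text{split},i}]$, and
   the per-site posterior
   $\rho L_{\text{split},i} / [(1-\rho)L_{\text{linked},i} + \rho
   L_{\text{split},i}]$, smoothed by a conservation window, is thresholded at
   0.5.
2. **Group similarity (GroupSim-style).** Per column,
   $\mathrm{raw}(c) = \tfrac{w_A + w_B}{2}\,(1 - b)$ where $w_g$ is the mean
   normalized BLOSUM62 similarity over residue pairs within group $g$ and $b$
   the mean across groups; high when both groups are internally conserved but
   mutually dissimilar. Columns are ignored only when fully gapped; the
   smoothed score is thresholded at 0.5.
3. **Trace difference (Difference Evolutionary-Trace-style).** Each sequence
   set gets a per-column importance rank
   $1 + \sum_{n} \tfrac1n \sum_{g} H_g(c)$ over nested root-ward tree
   partitions ($H_g$ = within-group Shannon entropy, gap as a 21st symbol).
   A site is called when it is in the top 20% of either subgroup's ranking
   but not in the top 20% of the full set's ranking.

Sites called in both contrasts are classified from group consensus residues
as `CONVERGENT_IDENTICAL`, `CONVERGENT_SIMILAR`, or `PATTERN_ONLY`.

## Worked example

The `analysis/` directory is a four-stage, fully seeded workflow over the
package:

```sh
Rscript analysis/01_simulate.R      # synthetic 50-taxon, 400-column dataset
Rscript analysis/02_mask_filter.R   # masking, filters, taxon reduction
Rscript analysis/03_predictors.R    # contrasts + three predictors
Rscript analysis/04_convergence.R   # tallies, convergence classes, truth check
```

Output of a run (everything lands under `results/`):

```
simulated 50 sequences x 400 columns
planted columns: BACKGROUND = 300, MASK_BAIT = 20, TYPE1 = 40, TYPE2 = 40
masking: 376 of 400 columns kept (HIGH_GAP=17, LOW_RAW=3, LOW_WINDOW_MEAN=4 removed)
reduction: 6 short-branch taxa removed, 44 remain
[groupA] mixture: rho = 0.254, logL = -14017.1, 86 sites called
[groupA] group similarity: 20 sites called
[groupA] trace difference: 51 sites called
...
     method contrast_1 contrast_2 group1_only group2_only shared
1 DIFFTRACE     groupA    groupC1          26          25     25
2     FUNDI     groupA    groupC1          10          11     76
3  GROUPSIM     groupA    groupC1           1           2     19
92 sites called in both contrasts: CONVERGENT_IDENTICAL = 54, PATTERN_ONLY = 38
     method contrast recall    fpr
1     FUNDI   groupA  0.872 0.0604
...
```

Reading this: the simulator planted 20% divergent columns and the mixture
estimated rho ≈ 0.25 on each contrast; the mixture recovers ~87% of planted
sites at a ~6% false-positive rate; the group-similarity score calls far
fewer sites but with no false positives; most sites called in both contrasts
converged on the identical residue, as planted.

The same pipeline is available as one call:

```r
library(fdcontrast)
sim <- simulate_two_clade_tree(12, 12, 26, seed = 2026)
dat <- simulate_alignment(sim$tree, sim$groups, L = 400, seed = 2027)
res <- run_pipeline(dat$aln, sim$tree, sim$groups, "results/run",
                    default_config(seed = 1))
res$tally
```

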