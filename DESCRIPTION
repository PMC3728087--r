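Package: fdcontrast
Title: Contrast Analysis of Functional Divergence and Convergence in Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects functionally divergent and convergently evolved alignment
    positions between a focal protein subfamily and its background homologs.
    Implements confidence-score column masking of protein alignments,
    short-terminal-branch taxon reduction, contrast-partition construction on
    phylogenies, and three per-site predictors of functional divergence: a
    phylogenetic two-component mixture over linked versus severed-branch site
    likelihoods (Felsenstein pruning under JTT with discrete-gamma rates), an
    information-theoretic within-group versus between-group similarity score,
    and an evolutionary-trace style importance ranking with a top-fraction
    difference rule. Shared calls across two contrasts are classified as
    convergent-identical, convergent-similar, or pattern-only. A sequence
    simulator with planted rate-shift (Type I) and conserved-but-different
    (Type II) sites supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
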