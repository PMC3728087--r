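#!/usr/bin/env Rscript
# Stage 2: confidence-score column masking, sequence filters, taxon reduction.
#
# Columns are removed when raw support < 6, the size-seven window mean < 8,
# or the gap fraction exceeds 70%. Sequences covering < 75% of the trimmed
# alignment and exact duplicates are dropped. The background is then reduced
# by iteratively deleting a random leaf from the bottom 10% of the terminal
# branch length distribution (focal groups protected), emulating diversity
# thinning of an overrepresented sequence set.

suppressMessages(library(fdcontrast))
ind <- "results/sim"
out <- "results/masked"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- read_scored_alignment(file.path(ind, "alignment.fasta"),
                             file.path(ind, "support.tsv"))
tree <- ape::read.tree(file.path(ind, "tree.nwk"))
groups <- read_groups(file.path(ind, "groups.tsv"))
protected <- names(groups)[groups != "background"]

mask <- mask_columns(aln)
message("masking: ", length(mask$kept), " of ", aln_length(aln),
        " columns kept (",
        paste(names(table(mask$removed$reason)), table(mask$removed$reason),
              sep = "=", collapse = ", "), " removed)")
masked <- apply_mask(aln, mask)
write_mask_report(mask, file.path(out, "mask.tsv"),
                  n_columns = aln_length(aln))

n0 <- length(masked$ids)
masked <- filter_sequences(masked, min_coverage = 0.75,
                           protected = protected)
message("filters: ", length(masked$ids), " of ", n0, " sequences kept")
tree <- prune_to(tree, intersect(tree$tip.label, masked$ids))

red <- reduce_taxa(tree, masked, protected = protected,
                   target_size = 44, percentile = 0.10, seed = 2028)
message("reduction: ", nrow(red$removal_log), " short-branch taxa removed, ",
        length(red$tree$tip.label), " remain")
utils::write.table(red$removal_log, file.path(out, "removed_taxa.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ape::write.tree(red$tree, file.path(out, "tree.nwk"))
write_scored_alignment(red$aln, file.path(out, "alignment.fasta"),
                       file.path(out, "support.tsv"))
message("wrote ", out, "/{mask.tsv,removed_taxa.tsv,tree.nwk,alignment.fasta,support.tsv}")
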