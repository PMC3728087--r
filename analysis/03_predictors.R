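#!/usr/bin/env Rscript
# Stage 3: contrast construction and the three per-site predictors.
#
# Each focal clade is contrasted against the background with the other focal
# clade pruned. On each contrast we run: (1) the linked/severed two-component
# mixture with JTT + gamma(1, K = 4) and conservation-window smoothing of the
# per-site posteriors (0.5 call threshold); (2) the within/between group
# similarity score (0.5 threshold); (3) the evolutionary-trace difference
# rule (top 20%). One TSV per method and contrast lands in
# results/predictors/.

suppressMessages(library(fdcontrast))
ind <- "results/masked"
out <- "results/predictors"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- read_scored_alignment(file.path(ind, "alignment.fasta"),
                             file.path(ind, "support.tsv"))
tree <- ape::read.tree(file.path(ind, "tree.nwk"))
groups <- read_groups(file.path("results/sim", "groups.tsv"))
groups <- groups[names(groups) %in% aln$ids]

model <- substitution_model()
gamma <- discretize_gamma(1, 4)
sim_tab <- similarity_table()

for (ct in make_contrasts(tree, groups)) {
  id <- ct$contrast_id
  sub <- aln_subset(aln, ids = intersect(aln$ids, ct$tree$tip.label))

  fit <- fit_mixture(ct, sub, model, gamma, threshold = 0.5)
  message(sprintf("[%s] mixture: rho = %.3f, logL = %.1f, %d sites called",
                  id, fit$rho, fit$logL, sum(fit$sites$call)))
  write_score_table(fundi_score_table(fit, id),
                    file.path(out, paste0("fundi_", id, ".tsv")))

  gs <- set_contrast_id(
    groupsim_scores(sub, ct$group_a, ct$background, sim_tab,
                    threshold = 0.5), id)
  message(sprintf("[%s] group similarity: %d sites called", id,
                  sum(gs$call)))
  write_score_table(gs, file.path(out, paste0("groupsim_", id, ".tsv")))

  dt <- set_contrast_id(difference_calls(
    trace_ranks(ct$tree, sub, ct$group_a),
    trace_ranks(ct$tree, sub, ct$background),
    trace_ranks(ct$tree, sub, ct$tree$tip.label),
    top_fraction = 0.20), id)
  message(sprintf("[%s] trace difference: %d sites called", id,
                  sum(dt$call)))
  write_score_table(dt, file.path(out, paste0("difftrace_", id, ".tsv")))
}
message("wrote ", out, "/{fundi,groupsim,difftrace}_{groupA,groupC1}.tsv")
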