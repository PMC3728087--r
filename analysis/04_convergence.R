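#!/usr/bin/env Rscript
# Stage 4: per-method tallies, convergence classification, truth evaluation.
#
# Calls are intersected across the two contrasts per method (group-1-only /
# group-2-only / shared), sites called in both contrasts by any method are
# classified as convergent-identical, convergent-similar or pattern-only
# from group consensus residues, and every predictor is scored against the
# planted truth (recall on Type I + Type II columns vs false-positive rate on
# background columns, mask-bait columns excluded).

suppressMessages(library(fdcontrast))
pred <- "results/predictors"
out <- "results/convergence"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

aln <- read_scored_alignment("results/masked/alignment.fasta")
groups <- read_groups("results/sim/groups.tsv")
groups <- groups[names(groups) %in% aln$ids]

read_table <- function(method, id) {
  df <- utils::read.delim(file.path(pred, paste0(tolower(method), "_", id,
                                                 ".tsv")))
  site_score_table(method = method, contrast_id = id, site = df$site,
                   score = df$score, call = df$call, extra = NULL)
}
tables <- list()
for (m in c("FUNDI", "GROUPSIM", "DIFFTRACE"))
  for (id in c("groupA", "groupC1"))
    tables <- c(tables, list(read_table(m, id)))

tally <- tally_calls(tables)
print(tally)
utils::write.table(tally, file.path(out, "tally.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

shared <- shared_call_sites(tables)
conv <- classify_convergence(aln, groups, shared)
message(length(shared), " sites called in both contrasts: ",
        paste(names(table(conv$classification)), table(conv$classification),
              sep = " = ", collapse = ", "))
utils::write.table(conv, file.path(out, "convergence.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# evaluate against the planted truth, mapped through the mask
mask <- utils::read.delim("results/masked/mask.tsv")
truth_all <- utils::read.delim("results/sim/truth.tsv")
truth <- truth_all$site_class[mask$column[mask$kept == 1]]
evals <- do.call(rbind, lapply(tables, function(t) {
  keepable <- truth != "MASK_BAIT"
  planted <- truth %in% c("TYPE1", "TYPE2")
  data.frame(method = attr(t, "method"),
             contrast = attr(t, "contrast_id"),
             recall = mean(t$call[planted & keepable]),
             fpr = mean(t$call[truth == "BACKGROUND"]))
}))
print(evals, digits = 3)
utils::write.table(format(evals, digits = 4),
                   file.path(out, "truth_evaluation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out, "/{tally.tsv,convergence.tsv,truth_evaluation.tsv}")
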