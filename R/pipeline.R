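#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: masking window 7 with
#' raw/mean support minima 6 and 8 on the 0-10 scale and 0.70 maximum gap
#' fraction; 0.75 minimum sequence coverage; 0.10 short-terminal-branch
#' percentile for taxon reduction; gamma shape 1 with 4 rate categories for
#' the mixture; 0.5 call thresholds for the mixture and group-similarity
#' predictors; 0.20 top fraction for the trace difference rule; 0.7 consensus
#' and 0.6 similarity cutoffs for convergence classification; size-seven
#' (half-width 3) conservation window with blend weight 0.3.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    window_size = 7L, raw_min = 6, mean_min = 8, gap_max_fraction = 0.70,
    min_coverage = 0.75,
    target_size = NULL, percentile = 0.10,
    alpha = 1, k_categories = 4L,
    fd_threshold = 0.5, top_fraction = 0.20,
    consensus_min = 0.7, similar_min = 0.6,
    half_width = 3L, lambda_mix = 0.3,
    smooth = TRUE, weights = NULL,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

stage_log <- function(run_log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  c(run_log, msg)
}

#' Run the full contrast analysis pipeline
#'
#' Executes, in order: column masking, sequence filtering,
#' short-terminal-branch taxon reduction (skipped unless `target_size` is
#' set), contrast construction, the three per-site predictors on each
#' contrast (mixture, group similarity, trace difference), the per-method
#' call tally, and convergence classification of sites called in both
#' contrasts. Every stage's parameters and counts are logged; all outputs are
#' written as TSV/JSON under `out_dir` together with the serialized
#' configuration and an MD5 manifest, so a rerun with the same inputs and
#' configuration is byte-identical.
#'
#' @param aln A `scored_alignment` with support scores (master alignment).
#' @param tree A rooted "phylo" tree over (a superset of) the alignment ids.
#' @param groups Named character vector id -> group (`"background"` plus one
#'   or two focal groups).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list from [default_config()].
#' @return Invisibly, a list with `masked_aln`, `tree`, `contrasts`,
#'   `tables` (all `site_score_table`s), `tally`, `convergence`, `log`.
#' @export
run_pipeline <- function(aln, tree, groups, out_dir,
                         config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_log <- character(0)
  protected <- names(groups)[groups != "background"]

  # 1. column masking
  mask <- mask_columns(aln, config$window_size, config$raw_min,
                       config$mean_min, config$gap_max_fraction)
  masked <- apply_mask(aln, mask)
  run_log <- stage_log(run_log, "mask", length(mask$kept), " of ",
                       aln_length(aln), " columns kept")
  write_mask_report(mask, file.path(out_dir, "mask.tsv"),
                    n_columns = aln_length(aln))

  # 2. sequence filters (coverage, duplicates)
  n_before <- length(masked$ids)
  masked <- filter_sequences(masked, config$min_coverage,
                             protected = protected)
  run_log <- stage_log(run_log, "filter", length(masked$ids), " of ",
                       n_before, " sequences kept")
  tree <- prune_to(tree, intersect(tree$tip.label, masked$ids))
  masked <- aln_subset(masked, ids = intersect(masked$ids, tree$tip.label))

  # 3. taxon reduction
  if (!is.null(config$target_size) &&
      config$target_size < length(tree$tip.label)) {
    red <- reduce_taxa(tree, masked, protected = protected,
                       target_size = config$target_size,
                       percentile = config$percentile, seed = config$seed)
    tree <- red$tree
    masked <- red$aln
    utils::write.table(red$removal_log,
                       file.path(out_dir, "removed_taxa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    run_log <- stage_log(run_log, "reduce", nrow(red$removal_log),
                         " taxa removed, ", length(tree$tip.label), " remain")
  } else {
    run_log <- stage_log(run_log, "reduce",
                         "no-op (target_size not below current leaf count)")
  }
  write_scored_alignment(masked, file.path(out_dir, "masked.fasta"),
                         file.path(out_dir, "masked_support.tsv"))

  # 4. contrasts
  groups <- groups[names(groups) %in% masked$ids]
  contrasts <- make_contrasts(tree, groups)
  run_log <- stage_log(run_log, "contrast", length(contrasts),
                       " contrasts: ",
                       paste(vapply(contrasts, `[[`, "", "contrast_id"),
                             collapse = ", "))
  model <- substitution_model()
  gamma <- discretize_gamma(config$alpha, config$k_categories)
  sim <- similarity_table()

  # 5. predictors per contrast
  tables <- list()
  for (ct in contrasts) {
    id <- ct$contrast_id
    sub_aln <- aln_subset(masked, ids = intersect(masked$ids,
                                                  ct$tree$tip.label))
    fit <- fit_mixture(ct, sub_aln, model, gamma,
                       threshold = config$fd_threshold,
                       smooth = config$smooth, sim = sim,
                       half_width = config$half_width,
                       lambda_mix = config$lambda_mix)
    ft <- fundi_score_table(fit, id)
    run_log <- stage_log(run_log, "fundi", id, ": rho = ",
                         sprintf("%.4f", fit$rho), ", ",
                         sum(ft$call), " sites called")
    gs <- set_contrast_id(
      groupsim_scores(sub_aln, ct$group_a, ct$background, sim,
                      weights = config$weights,
                      threshold = config$fd_threshold,
                      smooth = config$smooth,
                      half_width = config$half_width,
                      lambda_mix = config$lambda_mix), id)
    run_log <- stage_log(run_log, "groupsim", id, ": ",
                         sum(gs$call), " sites called")
    dt <- set_contrast_id(difference_calls(
      trace_ranks(ct$tree, sub_aln, ct$group_a),
      trace_ranks(ct$tree, sub_aln, ct$background),
      trace_ranks(ct$tree, sub_aln, ct$tree$tip.label),
      top_fraction = config$top_fraction), id)
    run_log <- stage_log(run_log, "difftrace", id, ": ",
                         sum(dt$call), " sites called")
    for (t in list(ft, gs, dt))
      write_score_table(t, file.path(out_dir, sprintf(
        "%s_%s.tsv", tolower(attr(t, "method")), id)))
    tables <- c(tables, list(ft, gs, dt))
  }

  # 6. tally and convergence classification (needs two contrasts)
  tally <- NULL
  conv <- NULL
  if (length(contrasts) == 2L) {
    tally <- tally_calls(tables)
    utils::write.table(tally, file.path(out_dir, "tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    shared <- shared_call_sites(tables)
    conv <- classify_convergence(masked, groups, shared,
                                 consensus_min = config$consensus_min,
                                 sim = sim,
                                 similar_min = config$similar_min)
    utils::write.table(conv, file.path(out_dir, "convergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    run_log <- stage_log(run_log, "converge", length(shared),
                         " shared sites classified")
  }

  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(run_log, file.path(out_dir, "run_log.txt"))
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(masked_aln = masked, tree = tree, contrasts = contrasts,
                 tables = tables, tally = tally, convergence = conv,
                 log = run_log))
}
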