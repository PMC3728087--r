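#' Construct a site score table
#'
#' Common container for per-site scores and binary functional-divergence
#' calls from any predictor, in master alignment coordinates.
#'
#' @param method One of `"FUNDI"`, `"GROUPSIM"`, `"DIFFTRACE"`.
#' @param contrast_id Identifier of the contrast the table belongs to.
#' @param site Integer column indices.
#' @param score Numeric scores (NA allowed).
#' @param call Logical calls; a call is never made on an `NA` score.
#' @param params List of method parameters used.
#' @param extra Optional data.frame of method-specific columns.
#' @return Data.frame of class `site_score_table` with attributes `method`,
#'   `contrast_id`, `params`.
#' @export
site_score_table <- function(method, contrast_id, site, score, call,
                             params = list(), extra = NULL) {
  method <- match.arg(method, c("FUNDI", "GROUPSIM", "DIFFTRACE"))
  stopifnot(length(site) == length(score), length(site) == length(call))
  if (any(call & is.na(score)))
    stop("a call requires a non-NA score")
  df <- data.frame(site = site, score = score, call = call)
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, method = method, contrast_id = contrast_id, params = params,
            class = c("site_score_table", "data.frame"))
}

#' Set the contrast id on a score table
#' @param table A `site_score_table`.
#' @param contrast_id New contrast identifier.
#' @return The table with its `contrast_id` attribute replaced.
#' @export
set_contrast_id <- function(table, contrast_id) {
  attr(table, "contrast_id") <- contrast_id
  table
}

#' Write a site score table as TSV
#' @param table A `site_score_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tally functional-divergence calls across two contrasts per method
#'
#' For each method present, with exactly two contrasts: counts columns called
#' only in the first contrast, only in the second, and in both (the shape of
#' a group1-only / group2-only / shared summary). Contrasts are ordered by
#' sorted contrast id.
#'
#' @param tables List of `site_score_table`s (two per method, same master
#'   alignment length).
#' @return Data.frame with columns `method`, `contrast_1`, `contrast_2`,
#'   `group1_only`, `group2_only`, `shared`.
#' @export
tally_calls <- function(tables) {
  methods <- vapply(tables, attr, character(1), "method")
  out <- lapply(sort(unique(methods)), function(m) {
    tt <- tables[methods == m]
    ids <- vapply(tt, attr, character(1), "contrast_id")
    if (length(tt) != 2L)
      stop("method ", m, " needs exactly two contrasts, got ", length(tt))
    tt <- tt[order(ids)]
    ids <- sort(ids)
    if (nrow(tt[[1L]]) != nrow(tt[[2L]]))
      stop("mismatched table lengths for method ", m)
    c1 <- tt[[1L]]$call
    c2 <- tt[[2L]]$call
    data.frame(method = m, contrast_1 = ids[1L], contrast_2 = ids[2L],
               group1_only = sum(c1 & !c2), group2_only = sum(c2 & !c1),
               shared = sum(c1 & c2))
  })
  do.call(rbind, out)
}

#' Sites called in both contrasts by at least one method
#'
#' @param tables List of `site_score_table`s (two contrasts per method).
#' @return Integer vector of master column indices called (by any method) in
#'   both contrasts.
#' @export
shared_call_sites <- function(tables) {
  ids <- vapply(tables, attr, character(1), "contrast_id")
  uids <- sort(unique(ids))
  if (length(uids) != 2L) stop("expected exactly two contrast ids")
  called <- lapply(uids, function(id) {
    sub <- tables[ids == id]
    sort(unique(unlist(lapply(sub, function(t) t$site[t$call]))))
  })
  intersect(called[[1L]], called[[2L]])
}

#' Classify shared divergent sites as convergent or pattern-only
#'
#' For each shared site c, the consensus of a group is its most frequent
#' non-gap residue if that residue's frequency (among the group's non-gap
#' residues) is at least `consensus_min`, else none. A site is
#' `CONVERGENT_IDENTICAL` when both focal consensuses exist, are equal, and
#' the background consensus is absent or different; `CONVERGENT_SIMILAR` when
#' both focal consensuses exist, differ, and their normalized similarity is
#' at least `similar_min`; otherwise `PATTERN_ONLY`.
#'
#' @param aln The master `scored_alignment`.
#' @param groups Named character vector id -> group (two focal groups plus
#'   `"background"`).
#' @param shared_sites Integer master column indices to classify.
#' @param consensus_min Consensus frequency cutoff in `(0.5, 1]`
#'   (default 0.7).
#' @param sim A `similarity_table` for the similar-residue rule.
#' @param similar_min Normalized similarity cutoff for
#'   `CONVERGENT_SIMILAR` (default 0.6).
#' @return Data.frame with one row per shared site: `site`, consensus residue
#'   and frequency per focal group and background, `classification`.
#' @export
classify_convergence <- function(aln, groups, shared_sites,
                                 consensus_min = 0.7,
                                 sim = similarity_table(),
                                 similar_min = 0.6) {
  if (!(consensus_min > 0.5 && consensus_min <= 1))
    stop("consensus_min must be in (0.5, 1]")
  focal <- sort(setdiff(unique(groups), "background"))
  if (length(focal) != 2L) stop("exactly two focal groups required")
  m <- aln_matrix(aln)
  group_rows <- lapply(c(focal, "background"), function(g)
    intersect(rownames(m), names(groups)[groups == g]))
  names(group_rows) <- c("a", "c1", "bg")

  consensus <- function(rows, c) {
    x <- m[rows, c]
    x <- x[x != "-" & x != "X"]
    if (!length(x)) return(list(res = NA_character_, freq = NA_real_))
    tab <- sort(table(x), decreasing = TRUE)
    freq <- tab[[1L]] / length(x)
    list(res = if (freq >= consensus_min) names(tab)[1L] else NA_character_,
         freq = freq)
  }

  rows <- lapply(as.integer(shared_sites), function(c) {
    ca <- consensus(group_rows$a, c)
    cc1 <- consensus(group_rows$c1, c)
    cbg <- consensus(group_rows$bg, c)
    cls <- if (!is.na(ca$res) && !is.na(cc1$res) && ca$res == cc1$res &&
               (is.na(cbg$res) || cbg$res != ca$res))
      "CONVERGENT_IDENTICAL"
    else if (!is.na(ca$res) && !is.na(cc1$res) && ca$res != cc1$res &&
             sim$values[ca$res, cc1$res] >= similar_min)
      "CONVERGENT_SIMILAR"
    else "PATTERN_ONLY"
    data.frame(site = c,
               consensus_a = ca$res, freq_a = ca$freq,
               consensus_c1 = cc1$res, freq_c1 = cc1$freq,
               consensus_bg = cbg$res, freq_bg = cbg$freq,
               classification = cls, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(site = integer(0), consensus_a = character(0),
                      freq_a = numeric(0), consensus_c1 = character(0),
                      freq_c1 = numeric(0), consensus_bg = character(0),
                      freq_bg = numeric(0), classification = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
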