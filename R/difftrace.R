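#' Evolutionary-trace style per-column importance ranks
#'
#' Restricts the tree to `leaf_set` and, for each partition level
#' n = 1..N-1 (N = number of leaves), partitions the leaves into groups by
#' cutting at the n-1 internal nodes closest to the root (ordered by
#' branch-length distance from the root, ties by topological depth, then by
#' postorder index); each leaf is assigned to its nearest cut-node ancestor
#' (or the residual root group). The importance rank of column c is
#' `rank(c) = 1 + sum_n (1/n) sum_g H_g(c)`, where `H_g(c)` is the Shannon
#' entropy (natural log) of the symbol distribution of column c within group
#' g, with gap (and `X`) counted as a 21st symbol. Lower rank = more
#' important; a column invariant across `leaf_set` has the minimum rank 1.
#' Columns that are all gaps within `leaf_set` are `NA`.
#'
#' @param tree A "phylo" tree containing `leaf_set`.
#' @param aln A `scored_alignment` covering `leaf_set`.
#' @param leaf_set Character vector of at least two tip labels.
#' @return A `trace_ranks`: list with `ranks` (numeric per column), `leaf_set`
#'   and `n_levels`.
#' @export
trace_ranks <- function(tree, aln, leaf_set) {
  leaf_set <- as.character(leaf_set)
  if (length(leaf_set) < 2L) stop("leaf_set must contain at least 2 leaves")
  tree <- prune_to(tree, leaf_set)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- tree$Nnode

  # internal nodes (excluding the root), ordered by distance from root
  dist_root <- ape::node.depth.edgelength(tree)
  # edge-count depth from root
  parent <- integer(n_tip + n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_depth <- integer(n_tip + n_node)
  # nodes in preorder: reverse postorder of edges
  for (e in rev(seq_len(nrow(tree$edge)))) {
    ch <- tree$edge[e, 2L]
    edge_depth[ch] <- edge_depth[tree$edge[e, 1L]] + 1L
  }
  postorder_index <- integer(n_tip + n_node)
  postorder_index[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  internals <- setdiff(seq_len(n_tip + n_node), c(seq_len(n_tip), root))
  ord <- internals[order(dist_root[internals], edge_depth[internals],
                         postorder_index[internals])]

  codes <- aln_codes(aln)[tree$tip.label, , drop = FALSE]
  codes[is.na(codes)] <- 21L
  L <- ncol(codes)
  all_gap <- apply(codes, 2L, function(x) all(x == 21L))

  # leaves under each internal node (for nearest-cut-ancestor assignment we
  # instead walk each leaf's ancestor chain)
  anc_chain <- lapply(seq_len(n_tip), function(tip) {
    chain <- integer(0)
    node <- tip
    while (node != root) {
      node <- parent[node]
      chain <- c(chain, node)
    }
    chain  # nearest first, root last
  })

  col_entropy <- function(rows) {
    # entropy per column for one group of leaves
    sub <- codes[rows, , drop = FALSE]
    apply(sub, 2L, function(x) {
      p <- tabulate(x, 21L)
      p <- p[p > 0] / length(x)
      -sum(p * log(p))
    })
  }

  ranks <- rep(1, L)
  N <- n_tip
  for (n in seq_len(N - 1L)) {
    cuts <- ord[seq_len(n - 1L)]
    grp <- vapply(anc_chain, function(chain) {
      hit <- chain[chain %in% cuts]
      if (length(hit)) hit[[1L]] else root
    }, integer(1))
    level_H <- numeric(L)
    for (g in unique(grp))
      level_H <- level_H + col_entropy(which(grp == g))
    ranks <- ranks + level_H / n
  }
  ranks[all_gap] <- NA_real_
  structure(list(ranks = ranks, leaf_set = sort(leaf_set),
                 n_levels = N - 1L),
            class = "trace_ranks")
}

#' @export
print.trace_ranks <- function(x, ...) {
  cat("trace_ranks over", length(x$leaf_set), "leaves,", x$n_levels,
      "levels; rank range", paste(signif(range(x$ranks, na.rm = TRUE), 4),
                                  collapse = " - "), "\n")
  invisible(x)
}

# top set of a trace: indices of the ceil(top_fraction * L_valid) smallest
# ranks among non-NA columns, ties broken by smaller column index
trace_top_set <- function(ranks, top_fraction) {
  valid <- which(!is.na(ranks))
  k <- ceiling(top_fraction * length(valid))
  if (k == 0L) return(integer(0))
  valid[order(ranks[valid], valid)][seq_len(k)]
}

#' Difference-rule functional divergence calls from trace ranks
#'
#' A column is called functionally divergent when it lies in the top
#' `top_fraction` most important columns (smallest ranks) of either subgroup
#' trace but not in the top `top_fraction` of the full-set trace. Each trace's
#' top set has exactly `ceiling(top_fraction * L_valid)` members (L_valid =
#' its non-NA columns; rank ties broken by smaller column index).
#'
#' @param rank_a,rank_b `trace_ranks` for the two subgroups.
#' @param rank_full `trace_ranks` over all sequences.
#' @param top_fraction Fraction in `(0, 1)` (default 0.20).
#' @return A `site_score_table` data.frame with columns `site`, `rank_a`,
#'   `rank_b`, `rank_full`, `top_a`, `top_b`, `top_full`, `call`; attribute
#'   `method = "DIFFTRACE"`.
#' @export
difference_calls <- function(rank_a, rank_b, rank_full, top_fraction = 0.20) {
  L <- length(rank_full$ranks)
  if (length(rank_a$ranks) != L || length(rank_b$ranks) != L)
    stop("trace rank vectors must have identical lengths")
  if (!(top_fraction > 0 && top_fraction < 1))
    stop("top_fraction must be in (0, 1)")
  in_top <- function(tr) seq_len(L) %in% trace_top_set(tr$ranks, top_fraction)
  top_a <- in_top(rank_a); top_b <- in_top(rank_b)
  top_full <- in_top(rank_full)
  call <- (top_a | top_b) & !top_full
  # score: the stronger (smaller) subgroup rank — defined wherever a call is
  best_sub <- pmin(rank_a$ranks, rank_b$ranks, na.rm = TRUE)
  site_score_table(method = "DIFFTRACE", contrast_id = NA_character_,
                   site = seq_len(L), score = best_sub, call = call,
                   params = list(top_fraction = top_fraction),
                   extra = data.frame(rank_a = rank_a$ranks,
                                      rank_b = rank_b$ranks,
                                      rank_full = rank_full$ranks,
                                      top_a = top_a, top_b = top_b,
                                      top_full = top_full))
}
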