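#' Terminal branch lengths of a tree
#'
#' @param tree An `ape` "phylo" tree with branch lengths.
#' @return Named numeric vector of terminal (pendant) branch lengths, one per
#'   tip, named by tip label.
#' @export
terminal_branch_lengths <- function(tree) {
  n_tip <- length(tree$tip.label)
  tip_edge <- match(seq_len(n_tip), tree$edge[, 2L])
  stats::setNames(tree$edge.length[tip_edge], tree$tip.label)
}

#' Prune a tree to a set of leaves
#'
#' Induced subtree on `keep`: degree-2 nodes created by pruning are collapsed
#' and their branch lengths summed, so path lengths between kept leaves are
#' preserved exactly.
#'
#' @param tree A "phylo" tree.
#' @param keep Character vector of tip labels to retain (nonempty).
#' @return The pruned "phylo" tree.
#' @export
prune_to <- function(tree, keep) {
  keep <- as.character(keep)
  if (!length(keep)) stop("keep must be nonempty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves in keep: ", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Iterative removal of short-terminal-branch taxa
#'
#' Repeats, until the leaf count reaches `target_size`: compute terminal
#' branch lengths of all non-protected leaves on the current (pruned) tree,
#' form the candidate set of leaves whose terminal branch length is at or
#' below the inclusive lower empirical `percentile` quantile (type-1 quantile)
#' of the non-protected terminal branch length distribution, and delete one
#' candidate uniformly at random. The tree is re-pruned (collapsing the
#' degree-2 node, summing branch lengths) and the sequence dropped from the
#' alignment; candidate pools are recomputed from the pruned tree each
#' iteration.
#'
#' RNG contract (so that runs can be replayed independently): the global RNG
#' is seeded once with `seed` on entry (the caller's RNG state is restored on
#' exit); at each iteration the candidate labels are sorted alphabetically and
#' one is chosen with a single `sample.int(n_candidates, 1)` draw.
#'
#' @param tree A "phylo" tree whose tips match `aln` ids.
#' @param aln A `scored_alignment` containing (at least) all tree tips.
#' @param protected Character vector of leaf labels never removed.
#' @param target_size Desired final leaf count (`>= length(protected)`).
#' @param percentile Lower quantile defining "short" terminal branches
#'   (default 0.10).
#' @param seed Integer seed (required).
#' @return List with `tree`, `aln` (both reduced) and `removal_log`, a
#'   data.frame of `iteration`, `removed_id`, `terminal_bl`.
#' @export
reduce_taxa <- function(tree, aln, protected = character(), target_size,
                        percentile = 0.10, seed) {
  if (missing(seed)) stop("seed must be provided")
  stopifnot(all(tree$tip.label %in% aln$ids))
  n0 <- length(tree$tip.label)
  if (target_size > n0) stop("target_size exceeds current leaf count")
  if (target_size < length(intersect(protected, tree$tip.label)))
    stop("target_size smaller than the protected set")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  log_it <- integer(0); log_id <- character(0); log_bl <- numeric(0)
  iter <- 0L
  while (length(tree$tip.label) > target_size) {
    iter <- iter + 1L
    tbl <- terminal_branch_lengths(tree)
    tbl <- tbl[!(names(tbl) %in% protected)]
    if (!length(tbl))
      stop("no removable (non-protected) leaves remain before reaching target")
    cut <- stats::quantile(tbl, percentile, type = 1, names = FALSE)
    cand <- sort(names(tbl)[tbl <= cut])
    victim <- cand[sample.int(length(cand), 1L)]
    log_it <- c(log_it, iter)
    log_id <- c(log_id, victim)
    log_bl <- c(log_bl, unname(tbl[victim]))
    tree <- ape::drop.tip(tree, victim)
  }
  list(tree = tree,
       aln = aln_subset(aln, ids = intersect(aln$ids, tree$tip.label)),
       removal_log = data.frame(iteration = log_it, removed_id = log_id,
                                terminal_bl = log_bl,
                                stringsAsFactors = FALSE))
}

#' Build contrast partitions: each focal group versus the background
#'
#' For every focal group (any group label other than `"background"`), builds
#' the contrast tree containing that group plus all background leaves, with
#' every other focal group's leaves pruned (degree-2 nodes collapsed, branch
#' lengths summed). Each focal group must be monophyletic in `tree` as rooted.
#' The branch separating the focal clade from the background (the branch above
#' the focal clade's most recent common ancestor in the pruned tree) is the
#' contrast's split branch.
#'
#' @param tree A rooted "phylo" tree; tips must be covered by `groups`.
#' @param groups Named character vector mapping tip label to group; the value
#'   `"background"` marks background leaves, all other values focal groups.
#' @return List of `contrast_spec` objects (one per focal group, in sorted
#'   group-label order), each with elements `contrast_id`, `tree`, `group_a`,
#'   `background`.
#' @export
make_contrasts <- function(tree, groups) {
  miss <- setdiff(tree$tip.label, names(groups))
  if (length(miss))
    stop("tips without group assignment: ", paste(miss, collapse = ", "))
  groups <- groups[tree$tip.label]
  focal <- sort(setdiff(unique(groups), "background"))
  if (!length(focal)) stop("no focal groups present")
  bg <- names(groups)[groups == "background"]
  if (!length(bg)) stop("no background leaves present")
  lapply(focal, function(g) {
    tips_g <- names(groups)[groups == g]
    if (length(tips_g) > 1L && !ape::is.monophyletic(tree, tips_g))
      stop("focal group '", g, "' is not monophyletic; offending leaves: ",
           paste(tips_g, collapse = ", "))
    ctree <- prune_to(tree, c(tips_g, bg))
    structure(list(contrast_id = g, tree = ctree, group_a = tips_g,
                   background = bg),
              class = "contrast_spec")
  })
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("contrast_spec '", x$contrast_id, "': |group_a| = ",
      length(x$group_a), ", |background| = ", length(x$background), "\n",
      sep = "")
  invisible(x)
}

#' Identify a contrast's split branch
#'
#' The edge of `contrast$tree` whose removal separates `group_a` from the
#' background: the edge subtending the focal clade's MRCA (or the terminal
#' edge, for a single-leaf focal group).
#'
#' @param contrast A `contrast_spec`.
#' @return List with `edge` (row index into `tree$edge`), `length`, and
#'   `mrca` (the focal clade's root node number).
#' @export
split_branch <- function(contrast) {
  tree <- contrast$tree
  tips <- contrast$group_a
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, tips)
  }
  edge <- match(node, tree$edge[, 2L])
  if (is.na(edge))
    stop("split branch not found: focal group spans the root")
  list(edge = edge, length = tree$edge.length[edge], mrca = node)
}
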