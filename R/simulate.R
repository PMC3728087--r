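# draw a random rooted topology with uniform branch lengths in [0.02, depth]
random_subtree <- function(n, prefix, depth) {
  t <- ape::rtree(n, rooted = TRUE, br = NULL)
  t$tip.label <- paste0(prefix, seq_len(n))
  t$edge.length <- stats::runif(nrow(t$edge), 0.02, depth)
  t
}

strip_newick <- function(tree) sub(";$", "", ape::write.tree(tree))

#' Simulate a one-clade contrast tree
#'
#' A rooted tree in which a focal clade of `n_a` leaves is attached by a
#' single branch to a background subtree of `n_bg` leaves; all branch lengths
#' are drawn uniformly in `[0.02, depth]` with the seeded generator. This
#' mirrors the contrast topology of one plastid-targeted subfamily against
#' its cytosolic homologs.
#'
#' @param n_a Focal clade size (>= 2).
#' @param n_bg Background size (>= 2).
#' @param depth Upper bound of the uniform branch-length draw (default 0.3
#'   expected substitutions per site; see the methods vignette).
#' @param seed Integer seed.
#' @return List with `tree` ("phylo") and `groups` (named character vector,
#'   focal leaves `"groupA"`, background `"background"`).
#' @export
simulate_tree <- function(n_a, n_bg, depth = 0.3, seed) {
  stopifnot(n_a >= 2, n_bg >= 2)
  if (missing(seed)) stop("seed must be provided")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  ta <- random_subtree(n_a, "A", depth)
  tb <- random_subtree(n_bg, "B", depth)
  bl <- stats::runif(2, 0.02, depth)
  tree <- ape::read.tree(text = sprintf("(%s:%.6f,%s:%.6f);",
                                        strip_newick(ta), bl[1L],
                                        strip_newick(tb), bl[2L]))
  groups <- stats::setNames(
    c(rep("groupA", n_a), rep("background", n_bg)),
    c(ta$tip.label, tb$tip.label))
  list(tree = tree, groups = groups)
}

#' Simulate a two-focal-clade tree for convergence analyses
#'
#' A rooted tree with two focal clades (labelled `"groupA"` and `"groupC1"`)
#' and a background subtree, arranged so each focal clade is monophyletic and
#' attached by a single branch: `((A), ((C1), BG))`. Used to exercise the
#' two-contrast convergence stage end-to-end.
#'
#' @param n_a,n_c1 Focal clade sizes (>= 2).
#' @param n_bg Background size (>= 2).
#' @param depth Upper bound of the uniform branch-length draw.
#' @param seed Integer seed.
#' @return List with `tree` and `groups` as in [simulate_tree()].
#' @export
simulate_two_clade_tree <- function(n_a, n_c1, n_bg, depth = 0.3, seed) {
  stopifnot(n_a >= 2, n_c1 >= 2, n_bg >= 2)
  if (missing(seed)) stop("seed must be provided")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  ta <- random_subtree(n_a, "A", depth)
  tc <- random_subtree(n_c1, "C", depth)
  tb <- random_subtree(n_bg, "B", depth)
  bl <- stats::runif(4, 0.02, depth)
  tree <- ape::read.tree(text = sprintf(
    "(%s:%.6f,(%s:%.6f,%s:%.6f):%.6f);",
    strip_newick(ta), bl[1L], strip_newick(tc), bl[2L],
    strip_newick(tb), bl[3L], bl[4L]))
  groups <- stats::setNames(
    c(rep("groupA", n_a), rep("groupC1", n_c1), rep("background", n_bg)),
    c(ta$tip.label, tc$tip.label, tb$tip.label))
  list(tree = tree, groups = groups)
}

# sample child states along the tree for a set of columns sharing one rate
# multiplier per column; returns tip-state matrix (tips x columns)
evolve_columns <- function(tree, model, rates) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  L <- length(rates)
  states <- matrix(NA_integer_, n_tip + tree$Nnode, L)
  states[root, ] <- sample.int(20L, L, replace = TRUE, prob = model$pi)
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder
    par <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    bl <- tree$edge.length[e]
    for (c in seq_len(L)) {
      P <- transition_prob(model, bl * rates[c])
      states[ch, c] <- sample.int(20L, 1L, prob = P[states[par, c], ])
    }
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# edges whose child lies strictly inside a focal clade (the branch above the
# clade MRCA — the split branch — is excluded, i.e. evolves at the
# background-side rate)
focal_edge_mask <- function(tree, focal_tips) {
  if (length(focal_tips) == 1L) return(rep(FALSE, nrow(tree$edge)))
  mrca <- ape::getMRCA(tree, focal_tips)
  tr <- stats::reorder(tree, "postorder")
  inside <- rep(FALSE, max(tr$edge))     # indexed by node id
  inside[mrca] <- TRUE
  for (e in rev(seq_len(nrow(tr$edge))))
    if (inside[tr$edge[e, 1L]]) inside[tr$edge[e, 2L]] <- TRUE
  # node ids are shared with the original edge ordering
  inside[tree$edge[, 2L]] & tree$edge[, 2L] != mrca
}

#' Simulate an alignment with planted functionally divergent columns
#'
#' Generates an alignment on `tree` with four column classes. `BACKGROUND`
#' columns draw a root state from the model's equilibrium frequencies and
#' evolve down the tree with a per-site rate drawn from Gamma(alpha, alpha).
#' `TYPE1` (rate-shift) columns evolve the same way except that edges inside
#' each focal clade use the site rate divided by `rate_shift` (conserved in
#' the focal group) while all other edges use it multiplied by `rate_shift`
#' (variable outside); the split branch itself uses the outside rate. `TYPE2`
#' (conserved-but-different) columns pick a residue pair (a, b) with
#' normalized similarity below 0.3; focal-clade leaves receive a and
#' background leaves b, each independently flipped to a random other residue
#' with probability `epsilon`. `MASK_BAIT` columns exist only to exercise
#' column masking: they violate either the raw-support rule (support drawn in
#' 0-5) or the gap rule (over 70% gaps); they are excluded from predictor
#' truth evaluation. Support scores of all other columns are drawn as uniform
#' integers in 8-10.
#'
#' @param tree A "phylo" tree (from [simulate_tree()] or
#'   [simulate_two_clade_tree()]).
#' @param groups Named character vector id -> group; every non-background
#'   group is a focal clade.
#' @param L Alignment length.
#' @param f_type1,f_type2 Fractions of TYPE1/TYPE2 columns
#'   (`f_type1 + f_type2 <= 0.5`); integer counts are `round(f * L)`.
#' @param rate_shift Rate factor (>= 1) for TYPE1 columns (default 8).
#' @param epsilon TYPE2 per-leaf flip probability in `[0, 0.2]`
#'   (default 0.02).
#' @param model A `substitution_model`.
#' @param alpha Gamma shape for per-site background rates (default 1).
#' @param seed Integer seed.
#' @param bait_fraction Fraction of MASK_BAIT columns (default 0.05).
#' @param sim Similarity table used to choose TYPE2 residue pairs.
#' @return List with `aln` (a `scored_alignment` with support scores),
#'   `truth` (a `truth_table`: `site_class` per column plus `params`).
#' @export
simulate_alignment <- function(tree, groups, L, f_type1 = 0.1, f_type2 = 0.1,
                               rate_shift = 8, epsilon = 0.02,
                               model = substitution_model(), alpha = 1,
                               seed, bait_fraction = 0.05,
                               sim = similarity_table()) {
  stopifnot(f_type1 + f_type2 <= 0.5, rate_shift >= 1,
            epsilon >= 0, epsilon <= 0.2)
  if (missing(seed)) stop("seed must be provided")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  focal_groups <- setdiff(unique(groups), "background")
  focal_tips_by_group <- lapply(focal_groups, function(g)
    intersect(tree$tip.label, names(groups)[groups == g]))
  focal_tips <- unlist(focal_tips_by_group)

  n1 <- round(f_type1 * L)
  n2 <- round(f_type2 * L)
  nb <- round(bait_fraction * L)
  if (n1 + n2 + nb > L) stop("class fractions exceed the alignment length")
  site_class <- rep("BACKGROUND", L)
  planted <- sample.int(L, n1 + n2 + nb)
  site_class[planted[seq_len(n1)]] <- "TYPE1"
  if (n2) site_class[planted[n1 + seq_len(n2)]] <- "TYPE2"
  if (nb) site_class[planted[n1 + n2 + seq_len(nb)]] <- "MASK_BAIT"

  rates <- stats::rgamma(L, shape = alpha, rate = alpha)
  tipmat <- matrix(NA_integer_, n_tip, L,
                   dimnames = list(tree$tip.label, NULL))

  # BACKGROUND + MASK_BAIT columns evolve at the plain site rate
  plain <- which(site_class %in% c("BACKGROUND", "MASK_BAIT"))
  if (length(plain))
    tipmat[, plain] <- evolve_columns(tree, model, rates[plain])

  # TYPE1: per-edge rate multipliers (focal-clade edges slowed, rest sped up)
  t1 <- which(site_class == "TYPE1")
  if (length(t1)) {
    inside <- Reduce(`|`, lapply(focal_tips_by_group, function(tips)
      focal_edge_mask(tree, tips)))
    shifted <- tree
    for (c in t1) {
      shifted$edge.length <- tree$edge.length *
        ifelse(inside, rates[c] / rate_shift, rates[c] * rate_shift)
      tipmat[, c] <- evolve_columns(shifted, model, 1)
    }
  }

  # TYPE2: conserved-but-different residue pair with low similarity
  t2 <- which(site_class == "TYPE2")
  if (length(t2)) {
    elig <- which(sim$values < 0.3 & upper.tri(sim$values), arr.ind = TRUE)
    if (!nrow(elig)) stop("no residue pair under the similarity cap")
    for (c in t2) {
      pair <- elig[sample.int(nrow(elig), 1L), ]
      col <- ifelse(tree$tip.label %in% focal_tips, pair[[1L]], pair[[2L]])
      flip <- stats::runif(n_tip) < epsilon
      if (any(flip))
        col[flip] <- vapply(col[flip], function(x)
          sample(setdiff(seq_len(20L), x), 1L), integer(1))
      tipmat[, c] <- col
    }
  }

  support <- sample(8:10, L, replace = TRUE)
  bait <- which(site_class == "MASK_BAIT")
  seqs_mat <- matrix(AA_ALPHABET[tipmat], n_tip, L,
                     dimnames = dimnames(tipmat))
  for (c in bait) {
    if (stats::runif(1) < 0.5) {
      support[c] <- sample(0:5, 1L)                 # LOW_RAW violation
    } else {
      n_gap <- ceiling(0.71 * n_tip) + 1L           # HIGH_GAP violation
      seqs_mat[sample.int(n_tip, min(n_gap, n_tip)), c] <- "-"
    }
  }

  aln <- scored_alignment(tree$tip.label,
                          apply(seqs_mat, 1L, paste, collapse = ""),
                          support)
  truth <- structure(list(
    site_class = site_class,
    params = list(f_type1 = f_type1, f_type2 = f_type2,
                  rate_shift = rate_shift, epsilon = epsilon,
                  alpha = alpha, bait_fraction = bait_fraction,
                  seed = seed)), class = "truth_table")
  list(aln = aln, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", paste(names(table(x$site_class)),
                            table(x$site_class), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write the truth labels as TSV
#' @param truth A `truth_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(site = seq_along(truth$site_class),
               site_class = truth$site_class),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
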