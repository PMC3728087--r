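# Independent reference implementations used as oracles. Each re-derives the
# quantity with explicit loops / exhaustive enumeration, never through the
# package's own code path.

# --- masking: re-apply the three column rules one column at a time ----------
brute_mask <- function(aln, window_size = 7L, raw_min = 6, mean_min = 8,
                       gap_max_fraction = 0.70) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  L <- ncol(m)
  half <- (window_size - 1L) / 2
  kept <- integer(0)
  removed <- integer(0)
  reason <- character(0)
  for (c in seq_len(L)) {
    win <- aln$support[max(1, c - half):min(L, c + half)]
    gf <- sum(m[, c] == "-") / nrow(m)
    r <- NULL
    if (aln$support[c] < raw_min) r <- "LOW_RAW"
    else if (mean(win) < mean_min) r <- "LOW_WINDOW_MEAN"
    else if (gf > gap_max_fraction) r <- "HIGH_GAP"
    if (is.null(r)) kept <- c(kept, c)
    else { removed <- c(removed, c); reason <- c(reason, r) }
  }
  list(kept = kept, removed = removed, reason = reason)
}

# --- likelihood: exhaustive sum over internal-node state assignments --------
enum_site_lik <- function(tree, aln, site, model, gamma) {
  tree <- stats::reorder(tree, "postorder")
  codes <- fdcontrast::aln_matrix(aln)[tree$tip.label, site]
  codes <- match(codes, fdcontrast:::AA_ALPHABET)
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):(n_tip + tree$Nnode)
  root <- n_tip + 1L
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  total <- 0
  for (k in seq_len(gamma$n_categories)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_prob(model, tree$edge.length[e] * gamma$rates[k]))
    probs <- model$pi[grid[, match(root, internals)]]
    for (e in seq_len(nrow(tree$edge))) {
      sp <- grid[, match(tree$edge[e, 1L], internals)]
      ch <- tree$edge[e, 2L]
      if (ch <= n_tip) {
        obs <- codes[ch]
        if (is.na(obs)) next   # missing data: sums to 1 over child states
        probs <- probs * Ps[[e]][cbind(sp, obs)]
      } else {
        probs <- probs * Ps[[e]][cbind(sp, grid[, match(ch, internals)])]
      }
    }
    total <- total + gamma$weights[k] * sum(probs)
  }
  total
}

# --- conswin: explicit double loop ------------------------------------------
loop_conswin <- function(scores, conservation, half_width = 3L,
                         lambda_mix = 0.3) {
  L <- length(scores)
  out <- rep(NA_real_, L)
  for (c in seq_len(L)) {
    if (is.na(scores[c])) next
    acc <- c();
    for (j in seq_len(L)) {
      if (j == c || abs(j - c) > half_width) next
      if (is.na(scores[j]) || is.na(conservation[j])) next
      acc <- c(acc, conservation[j])
    }
    out[c] <- if (length(acc))
      (1 - lambda_mix) * scores[c] + lambda_mix * mean(acc)
    else scores[c]
  }
  out
}

# --- evolutionary trace: materialize every level's partition by descendant
#     set subtraction -------------------------------------------------------
ref_trace_ranks <- function(tree, aln, leaf_set) {
  tree <- ape::keep.tip(tree, leaf_set)
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  root <- n_tip + 1L
  desc <- function(nd) {
    if (nd <= n_tip) return(po$tip.label[nd])
    ape::extract.clade(po, nd)$tip.label
  }
  dist_root <- ape::node.depth.edgelength(po)
  edepth <- integer(max(po$edge))
  for (e in rev(seq_len(nrow(po$edge))))
    edepth[po$edge[e, 2L]] <- edepth[po$edge[e, 1L]] + 1L
  poidx <- integer(max(po$edge))
  poidx[po$edge[, 2L]] <- seq_len(nrow(po$edge))
  internals <- setdiff((n_tip + 1L):(n_tip + po$Nnode), root)
  ord <- internals[order(dist_root[internals], edepth[internals],
                         poidx[internals])]
  m <- fdcontrast::aln_matrix(aln)[po$tip.label, , drop = FALSE]
  m[m == "X"] <- "-"
  L <- ncol(m)
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ranks <- rep(1, L)
  for (n in seq_len(n_tip - 1L)) {
    cuts <- ord[seq_len(n - 1L)]
    # groups: each leaf goes to the smallest cut-node clade containing it
    sets <- c(lapply(cuts, desc), list(po$tip.label))
    assigned <- character(0)
    groups <- list()
    for (s in sets[order(vapply(sets, length, 1L))]) {
      g <- setdiff(s, assigned)
      assigned <- c(assigned, g)
      if (length(g)) groups <- c(groups, list(g))
    }
    for (g in groups)
      ranks <- ranks + apply(m[g, , drop = FALSE], 2L, H) / n
  }
  allgap <- apply(m, 2L, function(x) all(x == "-"))
  ranks[allgap] <- NA_real_
  ranks
}

# --- difference rule: sorted index lists and set algebra --------------------
ref_difference_calls <- function(ra, rb, rf, top_fraction = 0.2) {
  topset <- function(r) {
    valid <- which(!is.na(r))
    k <- ceiling(top_fraction * length(valid))
    head(valid[order(r[valid], valid)], k)
  }
  ta <- topset(ra); tb <- topset(rb); tf <- topset(rf)
  sites <- seq_along(rf)
  (sites %in% union(ta, tb)) & !(sites %in% tf)
}

# --- small fixture builders -------------------------------------------------
rand_scored_aln <- function(n_seq, L, gap_prob = 0.1, seed = 1) {
  set.seed(seed)
  letters20 <- fdcontrast:::AA_ALPHABET
  m <- matrix(sample(c(letters20, "-"), n_seq * L, replace = TRUE,
                     prob = c(rep((1 - gap_prob) / 20, 20), gap_prob)),
              n_seq, L)
  scored_alignment(paste0("s", seq_len(n_seq)),
                   apply(m, 1L, paste, collapse = ""),
                   support = sample(0:10, L, replace = TRUE))
}

rand_tree <- function(n, seed = 1, min_bl = 0.05, max_bl = 0.5) {
  set.seed(seed)
  t <- ape::rtree(n)
  t$edge.length <- stats::runif(nrow(t$edge), min_bl, max_bl)
  t
}

aln_for_tree <- function(tree, L, seed = 1, gap_prob = 0.05) {
  a <- rand_scored_aln(length(tree$tip.label), L, gap_prob, seed)
  a$ids <- tree$tip.label
  a
}
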