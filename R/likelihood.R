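# Core pruning engine. Computes, for one rate multiplier, the per-site
# log-likelihood of all alignment columns on `tree` (any "phylo", rooted or
# with a basal multifurcation). `codes` is the integer residue matrix from
# aln_codes() restricted to the tree's tips; NA = missing ('-'/'X'), which
# contributes a conditional vector of ones. Columns of every propagated
# conditional are rescaled by their maximum, with the log-scales accumulated,
# so deep trees do not underflow.
prune_loglik_one_rate <- function(tree, codes, model, rate) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  L <- ncol(codes)
  root <- n_tip + 1L
  cond <- vector("list", n_tip + n_node)
  tip_rows <- match(tree$tip.label, rownames(codes))
  logscale <- numeric(L)
  # distinct branch lengths share one P matrix
  blen <- tree$edge.length * rate
  ub <- unique(blen)
  Pcache <- lapply(ub, function(t) transition_prob(model, t))
  Pidx <- match(blen, ub)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    if (child <= n_tip) {
      cc <- codes[tip_rows[child], ]
      Cc <- matrix(1, 20L, L)
      obs <- which(!is.na(cc))
      if (length(obs)) {
        Cc[, obs] <- 0
        Cc[cbind(cc[obs], obs)] <- 1
      }
    } else {
      Cc <- cond[[child]]
    }
    M <- Pcache[[Pidx[e]]] %*% Cc
    smax <- apply(M, 2L, max)
    smax[smax <= 0] <- 1
    M <- sweep(M, 2L, smax, "/")
    logscale <- logscale + log(smax)
    cond[[parent]] <- if (is.null(cond[[parent]])) M else cond[[parent]] * M
  }
  log(colSums(model$pi * cond[[root]])) + logscale
}

log_sum_exp_rows <- function(m) {
  # log-sum-exp across rows of a (K x L) matrix
  top <- apply(m, 2L, max)
  top[!is.finite(top)] <- 0
  top + log(colSums(exp(sweep(m, 2L, top, "-"))))
}

#' Per-site likelihoods under a substitution model with gamma rates
#'
#' Felsenstein pruning on a fixed tree: for each alignment column i,
#' `L_i = sum_k (1/K) sum_x pi_x Cond_x(root | rate r_k)`, with gaps and `X`
#' treated as missing data (conditional vector of ones). For a reversible
#' model the result does not depend on root placement. All-gap columns have
#' likelihood exactly 1 (log-likelihood 0).
#'
#' @param tree A "phylo" tree with finite branch lengths; every tip must have
#'   a sequence in `aln`.
#' @param aln A `scored_alignment` containing at least the tree's tips.
#' @param model A `substitution_model` (default JTT).
#' @param gamma A `gamma_rates` object (default alpha = 1, K = 4).
#' @return A `site_likelihoods`: list with `loglik` (numeric per site) and
#'   `lik` (`exp(loglik)`).
#' @export
site_likelihoods <- function(tree, aln, model = substitution_model(),
                             gamma = discretize_gamma(1, 4)) {
  miss <- setdiff(tree$tip.label, aln$ids)
  if (length(miss))
    stop("tree leaves without sequences: ", paste(miss, collapse = ", "))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  codes <- aln_codes(aln)[tree$tip.label, , drop = FALSE]
  K <- gamma$n_categories
  per_rate <- vapply(seq_len(K), function(k)
    prune_loglik_one_rate(tree, codes, model, gamma$rates[k]),
    numeric(ncol(codes)))
  per_rate <- matrix(per_rate, nrow = ncol(codes))  # L x K
  ll <- log_sum_exp_rows(t(per_rate) + log(gamma$weights))
  # missing-data convention: an all-gap column has likelihood exactly 1
  ll[colSums(!is.na(codes)) == 0L] <- 0
  structure(list(loglik = ll, lik = exp(ll)), class = "site_likelihoods")
}

#' @export
print.site_likelihoods <- function(x, ...) {
  cat("site_likelihoods:", length(x$loglik), "sites, total logL =",
      format(sum(x$loglik)), "\n")
  invisible(x)
}

#' Write per-site log-likelihoods as TSV
#' @param sl A `site_likelihoods`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_loglik <- function(sl, path) {
  utils::write.table(
    data.frame(site = seq_along(sl$loglik), logL = sl$loglik),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
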