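#' Per-column conservation from mean pairwise residue similarity
#'
#' The conservation of a column is the mean normalized similarity over all
#' unordered pairs of non-gap residues in the column (gaps and `X` skipped).
#' Columns with fewer than two non-gap residues are `NA`. This is the
#' conservation signal blended into scores by window smoothing, shared by the
#' mixture and group-similarity predictors.
#'
#' @param aln A `scored_alignment`.
#' @param sim A `similarity_table` (default min-max normalized BLOSUM62).
#' @return Numeric vector in `[0, 1]` (or `NA`), one value per column.
#' @export
conservation_scores <- function(aln, sim = similarity_table()) {
  codes <- aln_codes(aln)
  S <- sim$values
  dS <- diag(S)
  apply(codes, 2L, function(cc) {
    cc <- cc[!is.na(cc)]
    n <- length(cc)
    if (n < 2L) return(NA_real_)
    f <- tabulate(cc, 20L)
    tot <- (t(f) %*% S %*% f - sum(f * dS)) / 2
    tot / (n * (n - 1) / 2)
  })
}

#' Conservation-window smoothing of per-site scores
#'
#' Blends each site's score with the mean conservation of its neighbourhood:
#' `out_c = (1 - lambda_mix) * score_c + lambda_mix * mean(conservation_j)`
#' over sites `j != c` with `|j - c| <= half_width` (truncated at the edges).
#' Sites with `NA` scores stay `NA` and are excluded from their neighbours'
#' means, as are sites with `NA` conservation. A site with no valid neighbour
#' keeps its raw score.
#'
#' @param scores Numeric vector of per-site scores (may contain `NA`).
#' @param conservation Numeric vector in `[0, 1]` (may contain `NA`), same
#'   length.
#' @param half_width Non-negative integer window half-width (default 3,
#'   i.e. a size-seven window).
#' @param lambda_mix Blend weight on the conservation term, in `[0, 1)`
#'   (default 0.3).
#' @return Numeric vector of smoothed scores.
#' @export
conswin_smooth <- function(scores, conservation, half_width = 3L,
                           lambda_mix = 0.3) {
  if (length(scores) != length(conservation))
    stop("scores and conservation must have the same length")
  if (!(lambda_mix >= 0 && lambda_mix < 1))
    stop("lambda_mix must be in [0, 1)")
  L <- length(scores)
  valid <- !is.na(scores) & !is.na(conservation)
  out <- rep(NA_real_, L)
  for (c in which(!is.na(scores))) {
    idx <- max(1L, c - half_width):min(L, c + half_width)
    idx <- idx[idx != c & valid[idx]]
    out[c] <- if (length(idx))
      (1 - lambda_mix) * scores[c] + lambda_mix * mean(conservation[idx])
    else scores[c]
  }
  out
}

#' Fit the two-component linked/severed mixture over sites
#'
#' For each site i of the contrast alignment, computes the linked likelihood
#' `L_linked_i` on the intact contrast tree and the severed likelihood
#' `L_split_i = L_A_i * L_B_i`, where the focal-clade subtree A and background
#' subtree B are obtained by cutting the contrast's split branch (each
#' subtree's root conditional closed with the model's equilibrium
#' frequencies; a single-leaf subtree contributes its residue's equilibrium
#' frequency). The divergent-site fraction rho is estimated by bounded
#' one-dimensional maximization of
#' `sum_i log[(1 - rho) L_linked_i + rho L_split_i]` on `[0, 1]`
#' (tolerance 1e-8, endpoints checked), and per-site posteriors are
#' `rho L_split_i / [(1 - rho) L_linked_i + rho L_split_i]`. Calls are made by
#' thresholding the conservation-window smoothed posterior (smoothing can be
#' disabled, in which case the raw posterior is thresholded).
#'
#' @param contrast A `contrast_spec`.
#' @param aln A `scored_alignment` covering the contrast's leaves.
#' @param model A `substitution_model` (default JTT).
#' @param gamma A `gamma_rates` (default alpha = 1, K = 4).
#' @param threshold Call cutoff on the (smoothed) posterior (default 0.5).
#' @param rho Optional fixed mixture weight (diagnostic mode); when supplied,
#'   no optimization is performed.
#' @param smooth Apply conservation-window smoothing before thresholding
#'   (default `TRUE`).
#' @param sim Similarity table for the conservation signal.
#' @param half_width,lambda_mix Smoothing parameters, see
#'   [conswin_smooth()].
#' @return A `mixture_fit`: list with `rho`, `alpha`, `logL`, `threshold`,
#'   and `sites`, a data.frame of `site`, `loglik_linked`, `loglik_split`,
#'   `posterior`, `smoothed`, `call`.
#' @export
fit_mixture <- function(contrast, aln, model = substitution_model(),
                        gamma = discretize_gamma(1, 4), threshold = 0.5,
                        rho = NULL, smooth = TRUE, sim = similarity_table(),
                        half_width = 3L, lambda_mix = 0.3) {
  tree <- contrast$tree
  aln <- aln_subset(aln, ids = intersect(aln$ids, tree$tip.label))
  sb <- split_branch(contrast)
  ll_linked <- site_likelihoods(tree, aln, model, gamma)$loglik

  ll_sub <- function(tips) {
    if (length(tips) < 2L) {
      warning("subtree with a single leaf: likelihood from equilibrium ",
              "frequencies alone")
      cc <- aln_codes(aln)[tips, ]
      out <- rep(0, aln_length(aln))
      obs <- !is.na(cc)
      out[obs] <- log(model$pi[cc[obs]])
      return(out)
    }
    sub <- if (setequal(tips, contrast$group_a))
      ape::extract.clade(tree, sb$mrca)
    else
      ape::drop.tip(tree, setdiff(tree$tip.label, tips))
    site_likelihoods(sub, aln, model, gamma)$loglik
  }
  ll_split <- ll_sub(contrast$group_a) + ll_sub(contrast$background)

  mix_loglik <- function(r) {
    if (r <= 0) return(sum(ll_linked))
    if (r >= 1) return(sum(ll_split))
    sum(log_sum_exp_rows(rbind(log1p(-r) + ll_linked, log(r) + ll_split)))
  }
  if (is.null(rho)) {
    opt <- stats::optimize(mix_loglik, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, mix_loglik(0), mix_loglik(1))
    rho <- cand[which.max(vals)]
    logL <- max(vals)
  } else {
    logL <- mix_loglik(rho)
  }
  posterior <- if (rho <= 0) rep(0, length(ll_linked))
  else if (rho >= 1) rep(1, length(ll_linked))
  else rho / (rho + (1 - rho) * exp(ll_linked - ll_split))

  smoothed <- if (smooth)
    conswin_smooth(posterior, conservation_scores(aln, sim),
                   half_width, lambda_mix)
  else posterior
  structure(list(
    rho = rho, alpha = gamma$shape, logL = logL, threshold = threshold,
    sites = data.frame(site = seq_along(posterior),
                       loglik_linked = ll_linked, loglik_split = ll_split,
                       posterior = posterior, smoothed = smoothed,
                       call = !is.na(smoothed) & smoothed > threshold)
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: rho = %.4f, alpha = %g, logL = %.3f, %d/%d sites called\n",
              x$rho, x$alpha, x$logL, sum(x$sites$call), nrow(x$sites)))
  invisible(x)
}

#' Convert a mixture fit to a site score table
#'
#' @param fit A `mixture_fit`.
#' @param contrast_id Contrast identifier to record.
#' @return A `site_score_table` data.frame with columns `site`, `score`
#'   (smoothed posterior), `call`, and attributes `method = "FUNDI"`,
#'   `contrast_id`, `params`.
#' @export
fundi_score_table <- function(fit, contrast_id) {
  site_score_table(method = "FUNDI", contrast_id = contrast_id,
                   site = fit$sites$site, score = fit$sites$smoothed,
                   call = fit$sites$call,
                   params = list(rho = fit$rho, alpha = fit$alpha,
                                 threshold = fit$threshold),
                   extra = fit$sites[c("loglik_linked", "loglik_split",
                                       "posterior")])
}
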