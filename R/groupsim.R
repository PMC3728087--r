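#' Normalized residue similarity table
#'
#' A symmetric 20x20 similarity matrix min-max normalized to `[0, 1]` over
#' all 400 entries (the global minimum maps to 0, the global maximum to 1).
#' The default is BLOSUM62 restricted to the 20 standard residues; note that
#' after min-max normalization self-similarities `s(a, a)` are generally
#' below 1 (only the globally maximal entry reaches 1), and `s(a, a) >=
#' s(a, b)` is not guaranteed and not assumed anywhere.
#'
#' @param matrix Optional symmetric numeric 20x20 matrix in `AA_ALPHABET`
#'   order; default is BLOSUM62 from Biostrings.
#' @param name Identifier recorded on the table.
#' @return A `similarity_table`: list with `values` (normalized matrix) and
#'   `source_name`.
#' @export
similarity_table <- function(matrix = NULL, name = "BLOSUM62-normalized") {
  if (is.null(matrix)) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    matrix <- data_env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(20L, 20L)))
    stop("similarity matrix must be 20x20")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("similarity matrix must be symmetric")
  rng <- range(matrix)
  vals <- (matrix - rng[1L]) / (rng[2L] - rng[1L])
  dimnames(vals) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(values = vals, source_name = name),
            class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  cat("similarity_table:", x$source_name, "\n")
  invisible(x)
}

#' Position-based (Henikoff-style) sequence weights
#'
#' Each column contributes `1 / (r * s)` to the weight of a sequence, where
#' `r` is the number of distinct symbols in the column and `s` the number of
#' sequences carrying that sequence's symbol; gaps/`X` are treated as one
#' extra symbol class. Weights are normalized to mean 1.
#'
#' @param aln A `scored_alignment`.
#' @return Numeric vector of positive weights, named by sequence id.
#' @export
henikoff_weights <- function(aln) {
  codes <- aln_codes(aln)
  codes[is.na(codes)] <- 21L
  w <- numeric(nrow(codes))
  for (c in seq_len(ncol(codes))) {
    cc <- codes[, c]
    counts <- tabulate(cc, 21L)
    r <- sum(counts > 0L)
    w <- w + 1 / (r * counts[cc])
  }
  w <- w / mean(w)
  stats::setNames(w, rownames(codes))
}

#' Group-contrast similarity scores per column
#'
#' For each column c, computes the weighted mean similarity over unordered
#' non-gap residue pairs within group A (`within_a`), within group B
#' (`within_b`) and across the two groups (`between`), then the raw
#' group-contrast score
#' `raw(c) = ((within_a + within_b) / 2) * (1 - between(c))`:
#' high when both groups are internally conserved but mutually dissimilar.
#' Pairs involving a gap are skipped. Under the default gap policy a column
#' is `NA` only when it is all gaps (or when no within-group or between-group
#' pair exists at all); a within term with no pairs (a group with fewer than
#' two non-gap residues) is dropped from the within mean. With
#' `strict_groups = TRUE` any column where either group has fewer than two
#' non-gap residues is `NA` (logged via message).
#'
#' The final score is the conservation-window smoothed raw score; calls are
#' `score > threshold`.
#'
#' @param aln A `scored_alignment`.
#' @param group_a,group_b Disjoint id sets, each with at least two sequences
#'   present in `aln`.
#' @param sim A `similarity_table`.
#' @param weights Per-sequence positive weights named by id, the string
#'   `"henikoff"`, or `NULL` for uniform (default).
#' @param threshold Call cutoff on the smoothed score (default 0.5).
#' @param strict_groups Stricter NA rule, see above (default `FALSE`).
#' @param smooth Apply conservation-window smoothing (default `TRUE`).
#' @param half_width,lambda_mix Smoothing parameters, see [conswin_smooth()].
#' @return A `site_score_table` data.frame with columns `site`, `within_a`,
#'   `within_b`, `between`, `raw`, `score` (smoothed), `call`; attributes
#'   `method = "GROUPSIM"`, `params`.
#' @export
groupsim_scores <- function(aln, group_a, group_b, sim = similarity_table(),
                            weights = NULL, threshold = 0.5,
                            strict_groups = FALSE, smooth = TRUE,
                            half_width = 3L, lambda_mix = 0.3) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(intersect(group_a, aln$ids)) < 2L ||
      length(intersect(group_b, aln$ids)) < 2L)
    stop("each group needs at least 2 sequences present in the alignment")
  weights_label <- if (identical(weights, "henikoff")) "henikoff"
                   else if (is.null(weights)) "uniform" else "custom"
  if (identical(weights, "henikoff")) weights <- henikoff_weights(aln)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(aln$ids)), aln$ids)
  codes <- aln_codes(aln)
  S <- sim$values
  dS <- diag(S)
  ids_a <- intersect(aln$ids, group_a)
  ids_b <- intersect(aln$ids, group_b)

  # weighted residue profiles per column: f[x] = sum of weights of sequences
  # carrying residue x
  profile <- function(ids, c) {
    cc <- codes[ids, c]
    w <- weights[ids]
    obs <- !is.na(cc)
    f <- numeric(20L)
    if (any(obs)) {
      tt <- tapply(w[obs], cc[obs], sum)
      f[as.integer(names(tt))] <- tt
    }
    list(f = f, w2 = sum(w[obs]^2), wd = sum(w[obs]^2 * dS[cc[obs]]),
         n = sum(obs), wsum = sum(w[obs]))
  }
  within_mean <- function(p) {
    denom <- p$wsum^2 - p$w2
    if (p$n < 2L || denom <= 0) return(NA_real_)
    (drop(t(p$f) %*% S %*% p$f) - p$wd) / denom
  }

  L <- aln_length(aln)
  within_a <- within_b <- between <- raw <- rep(NA_real_, L)
  n_degenerate <- 0L
  for (c in seq_len(L)) {
    pa <- profile(ids_a, c)
    pb <- profile(ids_b, c)
    if (pa$n + pb$n == 0L) next                    # all gaps -> NA
    within_a[c] <- within_mean(pa)
    within_b[c] <- within_mean(pb)
    if (pa$n >= 1L && pb$n >= 1L)
      between[c] <- drop(t(pa$f) %*% S %*% pb$f) / (pa$wsum * pb$wsum)
    if (strict_groups && (pa$n < 2L || pb$n < 2L)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    withins <- c(within_a[c], within_b[c])
    if (all(is.na(withins)) || is.na(between[c])) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    raw[c] <- mean(withins, na.rm = TRUE) * (1 - between[c])
  }
  if (n_degenerate)
    message(n_degenerate,
            " columns with too few non-gap residues scored NA")
  score <- if (smooth)
    conswin_smooth(raw, conservation_scores(aln, sim), half_width, lambda_mix)
  else raw
  site_score_table(method = "GROUPSIM", contrast_id = NA_character_,
                   site = seq_len(L), score = score,
                   call = !is.na(score) & score > threshold,
                   params = list(threshold = threshold,
                                 strict_groups = strict_groups,
                                 weights = weights_label),
                   extra = data.frame(within_a = within_a,
                                      within_b = within_b,
                                      between = between, raw = raw))
}
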