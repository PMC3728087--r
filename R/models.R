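# Jones-Taylor-Thornton (1992) empirical amino-acid model: lower-triangle
# exchangeabilities (column-major, residue order AA_ALPHABET) and equilibrium
# frequencies, as distributed with PAML (jones.dat).
JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQ <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' Construct an empirical amino-acid substitution model
#'
#' Builds a general time-reversible rate matrix Q = S diag(pi) from a
#' symmetric exchangeability matrix S and equilibrium frequencies pi, with the
#' diagonal filled so rows sum to zero and the matrix rescaled so that the
#' expected number of substitutions per unit branch length is 1. Transition
#' probabilities are obtained from the symmetric eigendecomposition of
#' diag(sqrt(pi)) Q diag(1/sqrt(pi)), cached in the model object.
#'
#' @param name Model identifier; `"JTT"` (default) uses the packaged
#'   Jones-Taylor-Thornton exchangeabilities and frequencies. Any other name
#'   requires `exchangeabilities` and `frequencies`.
#' @param exchangeabilities Optional symmetric non-negative 20x20 matrix (or a
#'   lower-triangle vector of length 190, column-major) in `AA_ALPHABET`
#'   residue order.
#' @param frequencies Optional numeric vector of 20 equilibrium frequencies
#'   (normalized to sum to 1).
#' @return A `substitution_model`: list with `name`, `S`, `pi`, `Q` and the
#'   cached eigensystem.
#' @export
substitution_model <- function(name = "JTT", exchangeabilities = NULL,
                               frequencies = NULL) {
  if (is.null(exchangeabilities)) {
    if (!identical(name, "JTT"))
      stop("only 'JTT' is packaged; supply exchangeabilities and frequencies")
    exchangeabilities <- JTT_EXCH
    frequencies <- JTT_FREQ
  }
  S <- exchangeabilities
  if (is.null(dim(S))) {
    if (length(S) != 190L)
      stop("lower-triangle exchangeability vector must have length 190")
    M <- matrix(0, 20, 20)
    M[lower.tri(M)] <- S
    S <- M + t(M)
  }
  if (!isTRUE(all.equal(S, t(S))) || any(S < 0))
    stop("exchangeabilities must be symmetric and non-negative")
  pi <- frequencies / sum(frequencies)
  if (length(pi) != 20L || any(pi <= 0))
    stop("frequencies must be 20 positive numbers")
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  ps <- sqrt(pi)
  A <- diag(ps) %*% Q %*% diag(1 / ps)
  A <- (A + t(A)) / 2   # symmetrize against rounding
  eig <- eigen(A, symmetric = TRUE)
  structure(list(name = name, S = S, pi = pi, Q = Q,
                 eig_values = eig$values,
                 # pre-multiplied eigenvector factors: P(t) = L exp(D t) R
                 eig_left = diag(1 / ps) %*% eig$vectors,
                 eig_right = t(eig$vectors) %*% diag(ps)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model:", x$name, "(20-state GTR form, mean rate 1)\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' @param model A `substitution_model`.
#' @param t Non-negative branch length (expected substitutions per site).
#' @return 20x20 row-stochastic matrix; entries clamped at 0 against rounding.
#' @export
transition_prob <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P
}

#' Discretize a mean-one gamma distribution into equal-probability categories
#'
#' Category rates are the exact conditional means of Gamma(alpha, alpha) over
#' K equal-probability intervals, computed from the incomplete-gamma identity
#' E[X | a < X < b] proportional to the Gamma(alpha + 1, alpha) interval mass,
#' so the weighted mean rate is exactly 1.
#'
#' @param alpha Positive shape parameter.
#' @param K Positive integer number of categories.
#' @return A `gamma_rates`: list with `shape`, `n_categories`, `rates`,
#'   `weights` (each `1/K`).
#' @export
discretize_gamma <- function(alpha, K) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  breaks <- stats::qgamma(seq(0, 1, length.out = K + 1L),
                          shape = alpha, rate = alpha)
  # mean of Gamma(a, a) is 1, so category mean = K * mass under Gamma(a+1, a)
  mass <- diff(stats::pgamma(breaks, shape = alpha + 1, rate = alpha))
  structure(list(shape = alpha, n_categories = K, rates = K * mass,
                 weights = rep(1 / K, K)),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat("gamma_rates: alpha =", x$shape, ", K =", x$n_categories,
      ", rates =", paste(signif(x$rates, 4), collapse = " "), "\n")
  invisible(x)
}
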