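model <- substitution_model()

make_contrast_fixture <- function(n_a = 5, n_bg = 7, L = 30, seed = 1,
                                  f_type1 = 0, f_type2 = 0.2, ...) {
  sim <- simulate_tree(n_a, n_bg, seed = seed)
  dat <- simulate_alignment(sim$tree, sim$groups, L = L, f_type1 = f_type1,
                            f_type2 = f_type2, seed = seed + 1,
                            bait_fraction = 0, ...)
  ct <- make_contrasts(sim$tree, sim$groups)[[1L]]
  list(ct = ct, aln = dat$aln, truth = dat$truth)
}

test_that("conswin smoothing matches an explicit double-loop reference", {
  set.seed(4)
  for (rep in 1:5) {
    L <- 40
    scores <- runif(L)
    cons <- runif(L)
    scores[sample(L, 5)] <- NA
    cons[sample(L, 3)] <- NA
    mine <- conswin_smooth(scores, cons)
    expect_lt(max(abs(mine - loop_conswin(scores, cons)), na.rm = TRUE),
              1e-12)
    expect_equal(is.na(mine), is.na(scores))
  }
})

test_that("conswin limiting cases are exact", {
  scores <- runif(20)
  cons <- runif(20)
  expect_equal(conswin_smooth(scores, cons, lambda_mix = 0), scores)
  out <- conswin_smooth(rep(0.5, 20), rep(1, 20), lambda_mix = 0.3)
  expect_equal(out, rep(0.65, 20))
  expect_error(conswin_smooth(1:3, 1:4), "length")
})

test_that("posterior equals rho exactly where split and linked agree", {
  fx <- make_contrast_fixture(seed = 2)
  fit <- fit_mixture(fx$ct, fx$aln, model, discretize_gamma(1, 2),
                     smooth = FALSE)
  s <- fit$sites
  agree <- which(abs(s$loglik_split - s$loglik_linked) < 1e-14)
  if (length(agree))
    expect_equal(s$posterior[agree], rep(fit$rho, length(agree)))
  # algebraic identity checked directly by forcing equality
  fit0 <- fit_mixture(fx$ct, fx$aln, model, discretize_gamma(1, 2),
                      rho = 0.37, smooth = FALSE)
  d <- fit0$sites$loglik_split - fit0$sites$loglik_linked
  expect_equal(fit0$sites$posterior,
               0.37 / (0.37 + 0.63 * exp(-d)), tolerance = 1e-12)
})

test_that("fixing rho at zero gives zero posteriors and the linked logL", {
  fx <- make_contrast_fixture(seed = 3)
  fit <- fit_mixture(fx$ct, fx$aln, model, discretize_gamma(1, 2), rho = 0,
                     smooth = FALSE)
  expect_equal(fit$sites$posterior, rep(0, nrow(fit$sites)))
  expect_equal(fit$logL, sum(fit$sites$loglik_linked))
  expect_false(any(fit$sites$call))
})

test_that("rho maximization matches a fine grid-search oracle", {
  g <- discretize_gamma(1, 1)
  for (seed in c(5, 6, 7)) {
    fx <- make_contrast_fixture(n_a = 4, n_bg = 6, L = 30, seed = seed)
    fit <- fit_mixture(fx$ct, fx$aln, model, g, smooth = FALSE)
    ll_l <- fit$sites$loglik_linked
    ll_s <- fit$sites$loglik_split
    grid <- seq(0, 1, by = 0.001)
    obj <- vapply(grid, function(r) {
      if (r == 0) sum(ll_l) else if (r == 1) sum(ll_s)
      else sum(log((1 - r) * exp(ll_l) + r * exp(ll_s)))
    }, numeric(1))
    expect_lte(abs(fit$rho - grid[which.max(obj)]), 0.001)
    expect_gte(fit$logL, max(obj) - 1e-9)
    # the maximized logL dominates both endpoints
    expect_gte(fit$logL, obj[1])
    expect_gte(fit$logL, obj[length(grid)])
  }
})

test_that("posteriors increase with the split/linked likelihood ratio", {
  fx <- make_contrast_fixture(seed = 8)
  fit <- fit_mixture(fx$ct, fx$aln, model, discretize_gamma(1, 2),
                     smooth = FALSE)
  d <- fit$sites$loglik_split - fit$sites$loglik_linked
  ord <- order(d)
  expect_true(all(diff(fit$sites$posterior[ord]) >= -1e-12))
})

test_that("single-leaf focal subtrees fall back to equilibrium frequencies", {
  tr <- ape::read.tree(text = "(a:0.1,(b:0.2,(c:0.2,d:0.3):0.1):0.2);")
  groups <- c(a = "solo", b = "background", c = "background",
              d = "background")
  ct <- make_contrasts(tr, groups)[[1L]]
  aln <- scored_alignment(letters[1:4], c("W", "A", "A", "A"))
  g <- discretize_gamma(1, 1)
  expect_warning(
    fit <- fit_mixture(ct, aln, model, g, rho = 0.5, smooth = FALSE),
    "single leaf")
  w <- match("W", fdcontrast:::AA_ALPHABET)
  bg_ll <- site_likelihoods(prune_to(tr, c("b", "c", "d")),
                            aln, model, g)$loglik
  expect_equal(fit$sites$loglik_split, log(model$pi[w]) + bg_ll,
               tolerance = 1e-12)
})

test_that("planted divergent fraction is recovered within ±0.1", {
  rhos <- vapply(1:5, function(seed) {
    sim <- simulate_tree(10, 14, seed = seed)
    dat <- simulate_alignment(sim$tree, sim$groups, L = 150,
                              f_type1 = 0.1, f_type2 = 0.1, rate_shift = 8,
                              epsilon = 0.02, seed = seed + 50,
                              bait_fraction = 0)
    ct <- make_contrasts(sim$tree, sim$groups)[[1L]]
    fit_mixture(ct, dat$aln, model, discretize_gamma(1, 4),
                smooth = FALSE)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.2), 0.1)
})
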