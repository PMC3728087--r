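model <- substitution_model()

test_that("gamma discretization matches its closed forms and quadrature", {
  g1 <- discretize_gamma(2.7, 1)
  expect_equal(g1$rates, 1.0)
  g4 <- discretize_gamma(1, 4)
  expect_true(all(diff(g4$rates) > 0))
  expect_equal(sum(g4$rates * g4$weights), 1, tolerance = 1e-9)
  # quadrature oracle: numerically integrate x f(x) over each category
  g8 <- discretize_gamma(0.5, 8)
  breaks <- qgamma(seq(0, 1, length.out = 9), 0.5, 0.5)
  for (k in 1:8) {
    num <- integrate(function(x) x * dgamma(x, 0.5, 0.5),
                     breaks[k], breaks[k + 1], rel.tol = 1e-10)$value
    expect_equal(g8$rates[k], num * 8, tolerance = 1e-6)
  }
  expect_error(discretize_gamma(-1, 4), "alpha")
})

test_that("the rate matrix is properly normalized and reversible", {
  expect_equal(rowSums(model$Q), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(model$pi * diag(model$Q)), 1, tolerance = 1e-12)
  # detailed balance: pi_i Q_ij == pi_j Q_ji
  PQ <- model$pi * model$Q
  expect_equal(PQ, t(PQ), tolerance = 1e-12)
  P <- transition_prob(model, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10)
  expect_equal(transition_prob(model, 0), diag(20), tolerance = 1e-10)
})

test_that("a two-leaf identical site has likelihood pi_a * P_aa(t)", {
  tr <- ape::read.tree(text = "(x:0.15,y:0.25);")
  aln <- scored_alignment(c("x", "y"), c("W", "W"))
  g <- discretize_gamma(1, 1)
  sl <- site_likelihoods(tr, aln, model, g)
  a <- match("W", fdcontrast:::AA_ALPHABET)
  P <- transition_prob(model, 0.4)
  expect_equal(sl$lik, model$pi[a] * P[a, a], tolerance = 1e-12)
  # t -> infinity approaches pi_a^2
  tr2 <- ape::read.tree(text = "(x:300,y:300);")
  sl2 <- site_likelihoods(tr2, aln, model, g)
  expect_equal(sl2$lik, model$pi[a]^2, tolerance = 1e-8)
})

test_that("all-gap columns have likelihood exactly 1", {
  tr <- rand_tree(6, seed = 2)
  aln <- scored_alignment(tr$tip.label,
                          rep(paste0("A-", "X-"), 6) |> substr(1, 4))
  m <- aln_matrix(aln)
  m[, 2] <- "-"; m[, 4] <- "-"; m[, 3] <- "X"
  aln <- scored_alignment(aln$ids, apply(m, 1, paste, collapse = ""))
  sl <- site_likelihoods(tr, aln, model)
  expect_equal(sl$loglik[c(2, 3, 4)], rep(0, 3))
})

test_that("pruning equals exhaustive internal-state enumeration", {
  g <- discretize_gamma(0.8, 2)
  for (seed in 1:6) {
    tr <- rand_tree(4, seed)
    aln <- aln_for_tree(tr, 3, seed = seed + 100, gap_prob = 0.15)
    sl <- site_likelihoods(tr, aln, model, g)
    for (s in 1:3) {
      expect_equal(sl$lik[s], enum_site_lik(tr, aln, s, model, g),
                   tolerance = 1e-10)
    }
  }
})

test_that("site likelihoods are invariant to root placement (pulley)", {
  skip_if_not_installed("phytools")
  g <- discretize_gamma(1, 4)
  for (seed in 1:3) {
    tr <- rand_tree(8, seed)
    aln <- aln_for_tree(tr, 10, seed = seed, gap_prob = 0.1)
    base <- site_likelihoods(tr, aln, model, g)$loglik
    set.seed(seed)
    for (node in sample(9:15, 3)) {
      rr <- phytools::reroot(tr, node, position = 0.3 * tr$edge.length[
        match(node, tr$edge[, 2L])])
      expect_lt(max(abs(site_likelihoods(rr, aln, model, g)$loglik - base)),
                1e-8)
    }
  }
})

test_that("child-order swaps leave site likelihoods unchanged", {
  tr <- rand_tree(6, seed = 5)
  aln <- aln_for_tree(tr, 8, seed = 5)
  base <- site_likelihoods(tr, aln, model)$loglik
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(site_likelihoods(rot, aln, model)$loglik, base,
               tolerance = 1e-12)
})

test_that("total log-likelihood matches an independent pruning backend", {
  skip_if_not_installed("phangorn")
  tr <- rand_tree(10, seed = 8)
  aln <- aln_for_tree(tr, 40, seed = 8, gap_prob = 0.1)
  g <- discretize_gamma(1, 4)
  mine <- sum(site_likelihoods(tr, aln, model, g)$loglik)
  pd <- phangorn::phyDat(aln_matrix(aln), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 1)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("likelihood of a conserved column decays as branches stretch", {
  tr <- rand_tree(5, seed = 3)
  aln <- scored_alignment(tr$tip.label, rep("A", 5))
  lik_at <- function(scale) {
    t2 <- tr
    t2$edge.length <- tr$edge.length * scale
    site_likelihoods(t2, aln, model, discretize_gamma(1, 1))$loglik
  }
  vals <- vapply(c(1, 5, 25, 125), lik_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("leaves without sequences are reported", {
  tr <- rand_tree(4, seed = 1)
  aln <- scored_alignment(c("t1", "t2", "t3"), c("A", "A", "A"))
  expect_error(site_likelihoods(tr, aln), "without sequences")
})
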