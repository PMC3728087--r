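mk_table <- function(method, id, calls) {
  site_score_table(method = method, contrast_id = id,
                   site = seq_along(calls),
                   score = as.numeric(calls), call = calls)
}

test_that("tallies follow set arithmetic over the two contrasts", {
  f <- rep(FALSE, 10)
  t1 <- f; t1[c(3, 7)] <- TRUE
  t2 <- f; t2[c(7, 9)] <- TRUE
  tally <- tally_calls(list(mk_table("FUNDI", "g1", t1),
                            mk_table("FUNDI", "g2", t2)))
  expect_equal(tally$group1_only, 1L)
  expect_equal(tally$group2_only, 1L)
  expect_equal(tally$shared, 1L)
  empty <- tally_calls(list(mk_table("FUNDI", "g1", f),
                            mk_table("FUNDI", "g2", f)))
  expect_equal(unlist(empty[c("group1_only", "group2_only", "shared")]),
               c(group1_only = 0L, group2_only = 0L, shared = 0L))
})

test_that("tallies match a bitset oracle and are label-symmetric", {
  set.seed(5)
  for (rep in 1:5) {
    c1 <- runif(50) < 0.3
    c2 <- runif(50) < 0.3
    tally <- tally_calls(list(mk_table("GROUPSIM", "g1", c1),
                              mk_table("GROUPSIM", "g2", c2)))
    s1 <- which(c1); s2 <- which(c2)
    expect_equal(tally$shared, length(intersect(s1, s2)))
    expect_equal(tally$group1_only, length(setdiff(s1, s2)))
    expect_equal(tally$group2_only, length(setdiff(s2, s1)))
    swapped <- tally_calls(list(mk_table("GROUPSIM", "g1", c2),
                                mk_table("GROUPSIM", "g2", c1)))
    expect_equal(swapped$shared, tally$shared)
  }
})

test_that("shared sites are those called in both contrasts by any method", {
  f <- rep(FALSE, 10)
  fa <- f; fa[c(1, 2)] <- TRUE   # FUNDI contrast 1
  ga <- f; ga[3] <- TRUE         # GROUPSIM contrast 1
  fb <- f; fb[c(2, 3)] <- TRUE   # FUNDI contrast 2
  gb <- f                        # GROUPSIM contrast 2
  shared <- shared_call_sites(list(mk_table("FUNDI", "g1", fa),
                                   mk_table("GROUPSIM", "g1", ga),
                                   mk_table("FUNDI", "g2", fb),
                                   mk_table("GROUPSIM", "g2", gb)))
  expect_equal(shared, c(2L, 3L))
})

conv_aln <- function(col_a, col_c1, col_bg) {
  # one-column alignment with 5 seqs per group
  mk <- function(res) vapply(res, paste0, "", collapse = "")
  scored_alignment(
    c(paste0("a", 1:5), paste0("c", 1:5), paste0("g", 1:5)),
    c(mk(col_a), mk(col_c1), mk(col_bg)))
}

conv_groups <- c(setNames(rep("groupA", 5), paste0("a", 1:5)),
                 setNames(rep("groupC1", 5), paste0("c", 1:5)),
                 setNames(rep("background", 5), paste0("g", 1:5)))

test_that("strict conservation in both clades with varied background is convergent-identical", {
  # both plastid-type clades fixed for R, background mostly K (the Arg77-like
  # pattern)
  aln <- conv_aln(rep("R", 5), rep("R", 5), c("K", "K", "R", "A", "T"))
  out <- classify_convergence(aln, conv_groups, 1L)
  expect_equal(out$classification, "CONVERGENT_IDENTICAL")
  # both fixed for S against a proline-dominated background (Ser188-like)
  aln2 <- conv_aln(rep("S", 5), rep("S", 5), c("P", "P", "P", "P", "A"))
  out2 <- classify_convergence(aln2, conv_groups, 1L)
  expect_equal(out2$classification, "CONVERGENT_IDENTICAL")
  expect_equal(out2$consensus_bg, "P")
})

test_that("sub-threshold consensus frequencies yield pattern-only", {
  aln <- conv_aln(c("D", "D", "D", "A", "K"), rep("D", 5), rep("K", 5))
  out <- classify_convergence(aln, conv_groups, 1L, consensus_min = 0.7)
  expect_equal(out$classification, "PATTERN_ONLY")
  expect_true(is.na(out$consensus_a))
  # counting oracle: modal frequency is 3/5 = 0.6 < 0.7
  expect_equal(out$freq_a, 0.6)
})

test_that("different but similar consensus residues are convergent-similar", {
  # I and V: BLOSUM62 similarity 3 -> (3+4)/15 = 0.467 < 0.6 -> pattern only
  aln <- conv_aln(rep("I", 5), rep("V", 5), rep("P", 5))
  out <- classify_convergence(aln, conv_groups, 1L, similar_min = 0.4)
  expect_equal(out$classification, "CONVERGENT_SIMILAR")
  out2 <- classify_convergence(aln, conv_groups, 1L, similar_min = 0.6)
  expect_equal(out2$classification, "PATTERN_ONLY")
})

test_that("a background fixed for the same residue blocks the identical class", {
  aln <- conv_aln(rep("R", 5), rep("R", 5), rep("R", 5))
  out <- classify_convergence(aln, conv_groups, 1L)
  expect_equal(out$classification, "PATTERN_ONLY")
})

test_that("raising consensus_min never upgrades pattern-only to identical", {
  set.seed(8)
  cols <- replicate(30, sample(c("R", "K", "D", "-"), 15, replace = TRUE),
                    simplify = FALSE)
  aln <- scored_alignment(names(conv_groups),
                          vapply(seq_len(15), function(i)
                            paste(vapply(cols, `[`, "", i), collapse = ""),
                            ""))
  lo <- classify_convergence(aln, conv_groups, 1:30, consensus_min = 0.6)
  hi <- classify_convergence(aln, conv_groups, 1:30, consensus_min = 0.9)
  upgraded <- lo$classification == "PATTERN_ONLY" &
    hi$classification == "CONVERGENT_IDENTICAL"
  expect_false(any(upgraded))
})

test_that("every shared site receives exactly one classification", {
  set.seed(9)
  cols <- replicate(12, sample(c("A", "W", "D"), 15, replace = TRUE),
                    simplify = FALSE)
  aln <- scored_alignment(names(conv_groups),
                          vapply(seq_len(15), function(i)
                            paste(vapply(cols, `[`, "", i), collapse = ""),
                            ""))
  out <- classify_convergence(aln, conv_groups, 1:12)
  expect_equal(nrow(out), 12L)
  expect_true(all(out$classification %in%
    c("CONVERGENT_IDENTICAL", "CONVERGENT_SIMILAR", "PATTERN_ONLY")))
})
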