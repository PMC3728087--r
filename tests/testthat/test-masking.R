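test_that("column rules fire as specified on hand-built columns", {
  # col 1: raw support 5 -> LOW_RAW regardless of window context
  # col 4: 80% gaps -> HIGH_GAP; others clean
  aln <- scored_alignment(
    paste0("s", 1:5),
    c("ACDEF", "ACDEF", "ACD-F", "ACD-F", "ACD-F"),
    support = c(5, 10, 10, 10, 10))
  mk <- mask_columns(aln, window_size = 3, raw_min = 6, mean_min = 6,
                     gap_max_fraction = 0.5)
  expect_true(1 %in% mk$removed$column)
  expect_equal(mk$removed$reason[mk$removed$column == 1], "LOW_RAW")
  expect_true(4 %in% mk$removed$column)
  expect_equal(mk$removed$reason[mk$removed$column == 4], "HIGH_GAP")
})

test_that("an alignment with full support and no gaps keeps every column", {
  aln <- scored_alignment(c("a", "b"), c("ACDEF", "GHIKL"), rep(10, 5))
  mk <- mask_columns(aln)
  expect_equal(mk$kept, 1:5)
  expect_equal(nrow(mk$removed), 0L)
})

test_that("masking equals the brute-force three-rule oracle, incl. edges", {
  for (seed in 1:4) {
    aln <- rand_scored_aln(12, 200, gap_prob = 0.25, seed = seed)
    mk <- mask_columns(aln)
    or <- brute_mask(aln)
    expect_equal(mk$kept, or$kept)
    expect_equal(mk$removed$column, or$removed)
    expect_equal(mk$removed$reason, or$reason)
  }
  # alignments shorter than the window exercise edge truncation throughout
  short <- rand_scored_aln(6, 5, gap_prob = 0.2, seed = 9)
  mk <- mask_columns(short)
  or <- brute_mask(short)
  expect_equal(mk$kept, or$kept)
  expect_equal(mk$removed$reason, or$reason)
})

test_that("masking is independent of row order and monotone in thresholds", {
  aln <- rand_scored_aln(10, 120, gap_prob = 0.3, seed = 2)
  perm <- sample(seq_along(aln$ids))
  shuffled <- scored_alignment(aln$ids[perm], aln$seqs[perm], aln$support)
  expect_equal(mask_columns(aln)$kept, mask_columns(shuffled)$kept)
  base_kept <- length(mask_columns(aln)$kept)
  expect_lte(length(mask_columns(aln, raw_min = 8)$kept), base_kept)
  expect_lte(length(mask_columns(aln, mean_min = 9)$kept), base_kept)
  expect_lte(length(mask_columns(aln, gap_max_fraction = 0.5)$kept),
             base_kept)
})

test_that("re-masking an already-masked alignment removes no support columns", {
  set.seed(3)
  aln <- rand_scored_aln(10, 150, gap_prob = 0.2, seed = 3)
  support <- sample(8:10, 150, replace = TRUE)
  support[sample(150, 15)] <- sample(0:5, 15, replace = TRUE)
  aln <- scored_alignment(aln$ids, aln$seqs, support)
  masked <- apply_mask(aln, mask_columns(aln))
  again <- mask_columns(masked)
  expect_false(any(again$removed$reason %in% c("LOW_RAW")))
})

test_that("apply_mask subsets columns and supports exactly", {
  aln <- scored_alignment(c("a", "b"), c("ACD", "AFD"), c(7, 8, 9))
  out <- apply_mask(aln, list(kept = c(1L, 3L)))
  expect_equal(out$seqs, c("AD", "AD"))
  expect_equal(out$support, c(7, 9))
  ident <- apply_mask(aln, list(kept = 1:3))
  expect_equal(ident$seqs, aln$seqs)
  expect_error(apply_mask(aln, list(kept = c(1L, 9L))), "out of range")
})

test_that("complement mask reconstructs the original by interleaving", {
  set.seed(4)
  aln <- rand_scored_aln(8, 60, gap_prob = 0.2, seed = 4)
  support <- sample(8:10, 60, replace = TRUE)
  support[sample(60, 8)] <- sample(0:5, 8, replace = TRUE)
  aln <- scored_alignment(aln$ids, aln$seqs, support)
  mk <- mask_columns(aln)
  expect_gt(length(mk$kept), 0L)
  expect_gt(nrow(mk$removed), 0L)
  a1 <- apply_mask(aln, mk)
  a2 <- apply_mask(aln, list(kept = mk$removed$column))
  rebuilt <- matrix(NA_character_, length(aln$ids), aln_length(aln))
  rebuilt[, mk$kept] <- aln_matrix(a1)
  rebuilt[, mk$removed$column] <- aln_matrix(a2)
  expect_equal(apply(rebuilt, 1L, paste, collapse = ""),
               unname(aln$seqs))
})

test_that("missing support and bad windows are rejected", {
  aln <- scored_alignment(c("a", "b"), c("AC", "AC"))
  expect_error(mask_columns(aln), "support scores required")
  aln2 <- scored_alignment(c("a", "b"), c("AC", "AC"), c(9, 9))
  expect_error(mask_columns(aln2, window_size = 4), "odd")
  expect_error(mask_columns(aln2, window_size = 0), "odd")
})

test_that("coverage filter removes sequences below 75% non-gap", {
  L <- 100
  gappy <- paste(c(rep("A", 70), rep("-", 30)), collapse = "")
  full <- paste(rep("A", L), collapse = "")
  near <- paste(c(rep("C", 75), rep("-", 25)), collapse = "")
  aln <- scored_alignment(c("lo", "hi", "edge"), c(gappy, full, near))
  out <- filter_sequences(aln)
  expect_false("lo" %in% out$ids)      # 0.70 < 0.75
  expect_true(all(c("hi", "edge") %in% out$ids))  # 0.75 passes (>=)
})

test_that("duplicate collapsing prefers protected ids, else input order", {
  aln <- scored_alignment(c("a", "b", "c"), c("ACDE", "ACDE", "GHIK"))
  out <- filter_sequences(aln, protected = "b")
  expect_equal(out$ids, c("b", "c"))
  out2 <- filter_sequences(aln)
  expect_equal(out2$ids, c("a", "c"))
  # protected id failing coverage is removed, with a warning
  aln3 <- scored_alignment(c("p", "q"), c("A---", "ACDE"))
  expect_warning(filter_sequences(aln3, protected = "p"), "protected")
})

test_that("survivor count equals distinct rows passing coverage", {
  for (seed in 1:3) {
    set.seed(seed)
    base <- rand_scored_aln(10, 40, gap_prob = 0.15, seed = seed)
    dup_of <- sample(10, 4, replace = TRUE)
    aln <- scored_alignment(c(base$ids, paste0("d", 1:4)),
                            c(base$seqs, base$seqs[dup_of]),
                            base$support)
    out <- filter_sequences(aln, min_coverage = 0.6)
    cov_ok <- (1 - vapply(strsplit(aln$seqs, ""),
                          function(x) mean(x == "-"), 1)) >= 0.6
    expect_equal(length(out$ids), length(unique(aln$seqs[cov_ok])))
  }
})
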