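#' Mask alignment columns by confidence score and gap content
#'
#' Applies the three column-removal rules of confidence-score alignment
#' masking: a column is removed if (1) its raw support value is below
#' `raw_min`, (2) the mean support over a sliding window of `window_size`
#' columns centred on it (truncated at the alignment edges, centre included)
#' is below `mean_min`, or (3) its gap fraction strictly exceeds
#' `gap_max_fraction`. `X` counts as a non-gap character. Each removed column
#' is annotated with the first rule it violates, in the fixed order
#' `LOW_RAW`, `LOW_WINDOW_MEAN`, `HIGH_GAP`; the kept/removed partition itself
#' does not depend on that order.
#'
#' @param aln A `scored_alignment` with support scores present.
#' @param window_size Odd positive integer width of the sliding window
#'   (default 7).
#' @param raw_min Minimum raw support value (default 6, 0-10 scale).
#' @param mean_min Minimum window-mean support (default 8).
#' @param gap_max_fraction Maximum tolerated gap fraction; strictly greater is
#'   removed (default 0.70).
#'
#' @return A `mask_result`: list with `kept` (strictly increasing 1-based
#'   column indices), `removed` (data.frame of `column`, `reason`) and
#'   `params`.
#' @export
mask_columns <- function(aln, window_size = 7L, raw_min = 6, mean_min = 8,
                         gap_max_fraction = 0.70) {
  if (is.null(aln$support))
    stop("support scores required")
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L || window_size %% 2L == 0L)
    stop("window_size must be an odd positive integer")
  L <- aln_length(aln)
  s <- aln$support
  half <- (window_size - 1L) %/% 2L
  win_mean <- vapply(seq_len(L), function(c) {
    idx <- max(1L, c - half):min(L, c + half)
    mean(s[idx])
  }, numeric(1))
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")

  low_raw <- s < raw_min
  low_mean <- win_mean < mean_min
  high_gap <- gap_frac > gap_max_fraction
  removed_idx <- which(low_raw | low_mean | high_gap)
  reason <- ifelse(low_raw[removed_idx], "LOW_RAW",
                   ifelse(low_mean[removed_idx], "LOW_WINDOW_MEAN", "HIGH_GAP"))
  structure(list(
    kept = setdiff(seq_len(L), removed_idx),
    removed = data.frame(column = removed_idx, reason = reason,
                         stringsAsFactors = FALSE),
    params = list(window_size = window_size, raw_min = raw_min,
                  mean_min = mean_min, gap_max_fraction = gap_max_fraction)
  ), class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat("mask_result:", length(x$kept), "columns kept,",
      nrow(x$removed), "removed",
      sprintf("(%s)\n", paste(names(table(x$removed$reason)),
                              table(x$removed$reason),
                              sep = "=", collapse = ", ")))
  invisible(x)
}

#' Apply a column mask to an alignment
#'
#' @param aln A `scored_alignment`.
#' @param mask A `mask_result` (or any list with a `kept` integer vector).
#' @return The alignment restricted to the kept columns, support subset
#'   accordingly.
#' @export
apply_mask <- function(aln, mask) {
  kept <- as.integer(mask$kept)
  if (any(kept < 1L | kept > aln_length(aln)))
    stop("mask index out of range")
  aln_subset(aln, columns = kept)
}

#' Write a mask report as TSV
#'
#' One row per input column with a kept flag and, for removed columns, the
#' reason code.
#' @param mask A `mask_result`.
#' @param path Output TSV path.
#' @param n_columns Total number of columns of the masked alignment.
#' @return Invisibly, `path`.
#' @export
write_mask_report <- function(mask, path,
                              n_columns = length(mask$kept) + nrow(mask$removed)) {
  reason <- rep("", n_columns)
  reason[mask$removed$column] <- mask$removed$reason
  utils::write.table(
    data.frame(column = seq_len(n_columns),
               kept = as.integer(seq_len(n_columns) %in% mask$kept),
               reason = reason),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sequences by coverage and exact duplication
#'
#' Removes sequences covering less than `min_coverage` of the (trimmed)
#' alignment (non-gap fraction; `X` counts as coverage), then collapses groups
#' of byte-identical rows to a single survivor, preferring a protected id if
#' one is present in the group, else the first by input order. A protected id
#' that fails the coverage rule is still removed, with a warning.
#'
#' @param aln A `scored_alignment`.
#' @param min_coverage Minimum non-gap fraction in `(0, 1]` (default 0.75).
#' @param drop_exact_duplicates Collapse identical rows (default `TRUE`).
#' @param protected Character vector of ids preferred as duplicate-group
#'   survivors.
#' @return The filtered `scored_alignment` (possibly empty, with a warning).
#' @export
filter_sequences <- function(aln, min_coverage = 0.75,
                             drop_exact_duplicates = TRUE,
                             protected = character()) {
  if (!(min_coverage > 0 && min_coverage <= 1))
    stop("min_coverage must be in (0, 1]")
  L <- aln_length(aln)
  cov <- 1 - vapply(strsplit(aln$seqs, "", fixed = TRUE),
                    function(x) sum(x == "-"), numeric(1)) / L
  keep <- cov >= min_coverage
  dropped_protected <- intersect(aln$ids[!keep], protected)
  if (length(dropped_protected))
    warning("protected sequences removed by the coverage rule: ",
            paste(dropped_protected, collapse = ", "))
  ids <- aln$ids[keep]
  seqs <- aln$seqs[keep]
  if (drop_exact_duplicates && length(ids)) {
    survivors <- unlist(lapply(split(seq_along(seqs), seqs), function(idx) {
      prot <- idx[ids[idx] %in% protected]
      if (length(prot)) prot[[1L]] else idx[[1L]]
    }), use.names = FALSE)
    survivors <- sort(survivors)   # preserve input order
    ids <- ids[survivors]
    seqs <- seqs[survivors]
  }
  if (!length(ids)) {
    warning("no sequences left after filtering")
    return(structure(list(ids = character(), seqs = character(),
                          support = aln$support),
                     class = "scored_alignment"))
  }
  scored_alignment(ids, seqs, aln$support)
}
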