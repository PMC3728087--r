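# 20 standard residues in the conventional (PAML) order used by the
# substitution model and similarity tables throughout the package.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a scored protein alignment
#'
#' A `scored_alignment` holds an aligned set of amino-acid sequences together
#' with optional per-column alignment support scores on a 0-10 scale (the kind
#' of column confidence emitted by statistical aligners). It is the substrate
#' of column masking, sequence filtering, and all per-site scoring.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`),
#'   equal-length strings over the 20 amino-acid letters, `X` (ambiguous) and
#'   `-` (gap).
#' @param support Optional numeric vector of per-column support values, one per
#'   alignment column, each in `[0, 10]`. Values supplied on a `[0, 1]`
#'   posterior-probability scale are rescaled by 10 (with a message), since the
#'   masking thresholds are defined on the 0-10 scale.
#'
#' @return An object of class `scored_alignment` with elements `ids`, `seqs`
#'   and `support` (possibly `NULL`).
#' @export
scored_alignment <- function(ids, seqs, support = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("sequence ids must be unique")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must have identical length")
  if (L < 1L)
    stop("alignment length must be >= 1")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X-]"), seqs)
  if (any(bad))
    stop("sequences contain letters outside the amino-acid alphabet, 'X', '-': ",
         paste(ids[bad], collapse = ", "))
  if (!is.null(support)) {
    support <- as.numeric(support)
    if (length(support) != L)
      stop("support must have one value per alignment column")
    if (all(support >= 0 & support <= 1) && any(support > 0)) {
      # posterior-probability scale; masking thresholds assume 0-10
      if (max(support) <= 1) {
        message("support values look like [0,1] posteriors; rescaling by 10")
        support <- support * 10
      }
    }
    if (any(support < 0 | support > 10))
      stop("support values must lie in [0, 10]")
  }
  structure(list(ids = ids, seqs = seqs, support = support),
            class = "scored_alignment")
}

#' @export
print.scored_alignment <- function(x, ...) {
  cat("scored_alignment:", length(x$ids), "sequences x", aln_length(x),
      "columns;", if (is.null(x$support)) "no" else "with", "support scores\n")
  invisible(x)
}

#' Alignment length (number of columns)
#' @param aln A `scored_alignment`.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) nchar(aln$seqs[[1L]])

#' Alignment as a character matrix
#'
#' @param aln A `scored_alignment`.
#' @return Character matrix, rows = sequences (rownames = ids), columns =
#'   alignment positions.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Subset an alignment by sequences and/or columns
#'
#' @param aln A `scored_alignment`.
#' @param ids Sequence ids to keep (default all), in the order given.
#' @param columns Column indices to keep (default all), strictly as given.
#' @return A `scored_alignment`.
#' @export
aln_subset <- function(aln, ids = aln$ids, columns = seq_len(aln_length(aln))) {
  stopifnot(all(ids %in% aln$ids))
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("cannot subset to zero columns")
  if (any(columns < 1L | columns > aln_length(aln)))
    stop("column index out of range")
  m <- aln_matrix(aln)[ids, columns, drop = FALSE]
  scored_alignment(ids,
                   apply(m, 1L, paste, collapse = ""),
                   if (is.null(aln$support)) NULL else aln$support[columns])
}

# integer residue codes: 1..20 per AA_ALPHABET, NA for '-' / 'X' (missing)
aln_codes <- function(aln) {
  m <- aln_matrix(aln)
  codes <- match(m, AA_ALPHABET)
  dim(codes) <- dim(m)
  dimnames(codes) <- dimnames(m)
  codes
}

#' Read an aligned FASTA file, optionally with column support scores
#'
#' @param fasta Path to an aligned protein FASTA file.
#' @param scores Optional path to a tab-separated file of per-column support
#'   values with columns `column` (1-based index) and `support`.
#' @return A `scored_alignment`.
#' @export
read_scored_alignment <- function(fasta, scores = NULL) {
  ss <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(ss))
  support <- NULL
  if (!is.null(scores)) {
    tab <- utils::read.table(scores, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("column", "support") %in% names(tab)))
      stop("scores file must have columns 'column' and 'support'")
    support <- numeric(unique(Biostrings::width(ss)))
    support[tab$column] <- tab$support
  }
  scored_alignment(ids, as.character(ss), support)
}

#' Write an alignment to FASTA (and its support scores to TSV)
#'
#' @param aln A `scored_alignment`.
#' @param fasta Output FASTA path.
#' @param scores Optional output TSV path for the support scores.
#' @return Invisibly, `fasta`.
#' @export
write_scored_alignment <- function(aln, fasta, scores = NULL) {
  ss <- Biostrings::AAStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(scores)) {
    if (is.null(aln$support)) stop("alignment has no support scores to write")
    utils::write.table(
      data.frame(column = seq_along(aln$support), support = aln$support),
      scores, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a two-column group assignment table
#'
#' @param path TSV with columns `id` and `group`; groups are arbitrary labels,
#'   with `"background"` reserved for the background (outgroup) set.
#' @return Named character vector mapping id to group.
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(tab)))
    stop("groups file must have columns 'id' and 'group'")
  stats::setNames(tab$group, tab$id)
}

#' Write a group assignment table
#' @param groups Named character vector (names = ids, values = group labels).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(id = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
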