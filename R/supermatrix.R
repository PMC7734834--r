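#' Concatenate locus alignments into a supermatrix
#'
#' Builds a concatenated matrix over the (lexicographically sorted) union of
#' the input taxa, with per-gene partition coordinates. A taxon absent from a
#' gene has that gene's block filled entirely with `-`.
#'
#' @param alignments List of [gene_alignment()] objects, in the order their
#'   blocks should appear.
#' @return An object of class `supermatrix`: fields `taxa`, `seqs` (named
#'   concatenated strings) and `partitions`, a tibble with columns
#'   `locus_id`, `start`, `end` (1-based inclusive column coordinates that
#'   tile the matrix).
#' @export
concatenate <- function(alignments) {
  if (length(alignments) == 0) stop("need at least one alignment")
  ok <- vapply(alignments, inherits, TRUE, what = "gene_alignment")
  if (!all(ok)) stop("all elements must be gene_alignment objects")
  taxa <- sort(unique(unlist(lapply(alignments, function(a) a$taxa))),
               method = "radix")
  ids <- vapply(alignments, function(a) a$locus_id, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  lens <- vapply(alignments, function(a) a$length, 1L)
  end <- cumsum(lens)
  start <- end - lens + 1L
  blocks <- lapply(alignments, function(a) {
    filler <- strrep("-", a$length)
    out <- stats::setNames(rep(filler, length(taxa)), taxa)
    out[a$taxa] <- a$seqs
    out
  })
  seqs <- do.call(paste0, blocks)
  names(seqs) <- taxa
  structure(
    list(taxa = taxa, seqs = seqs, length = sum(lens),
         partitions = tibble::tibble(locus_id = ids, start = start, end = end)),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ", x$length, " columns, ",
      nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

#' Extract one partition of a supermatrix
#'
#' @param sm A [concatenate()] result.
#' @param locus_id Partition to extract.
#' @param drop_missing Drop taxa whose block is entirely `-` (taxa absent
#'   from the source gene)?
#' @return A [gene_alignment()].
#' @export
extract_partition <- function(sm, locus_id, drop_missing = TRUE) {
  stopifnot(inherits(sm, "supermatrix"))
  i <- match(locus_id, sm$partitions$locus_id)
  if (is.na(i)) stop("no partition named '", locus_id, "'")
  seqs <- substr(sm$seqs, sm$partitions$start[i], sm$partitions$end[i])
  names(seqs) <- sm$taxa
  if (drop_missing) {
    w <- sm$partitions$end[i] - sm$partitions$start[i] + 1L
    seqs <- seqs[seqs != strrep("-", w)]
  }
  gene_alignment(seqs, locus_id)
}

#' Write a RAxML-style partition table
#'
#' Plain-text lines of the form `DNA, <locus_id> = <start>-<end>` with
#' 1-based inclusive coordinates.
#'
#' @param sm A [concatenate()] result.
#' @param path Output path.
#' @export
write_partitions <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$locus_id,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}

# characters carrying full or partial missing information
UNDETERMINED_CHARS <- c("-", "N", "?", "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V")

#' Site-pattern and missing-data statistics
#'
#' Collapses identical alignment columns and reports the distinct-pattern
#' count, per-pattern weights, and the fraction of undetermined characters
#' (gaps `-`, `N`, `?`, and IUPAC ambiguity codes) in the matrix.
#'
#' @param x A [gene_alignment()] or [concatenate()] supermatrix.
#' @return A list of class `pattern_summary` with `distinct_patterns`,
#'   `total_columns`, `undetermined_fraction` and `pattern_weights` (integer
#'   counts in order of first appearance, summing to `total_columns`).
#' @export
compress_patterns <- function(x) {
  m <- aln_matrix(x)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix")
  cols <- apply(m, 2, paste0, collapse = "")
  first <- !duplicated(cols)
  weights <- as.integer(table(factor(cols, levels = cols[first])))
  undet <- sum(m %in% UNDETERMINED_CHARS) / length(m)
  structure(
    list(distinct_patterns = sum(first), total_columns = ncol(m),
         undetermined_fraction = undet,
         pattern_weights = stats::setNames(weights, cols[first])),
    class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("<pattern_summary> ", x$distinct_patterns, " distinct patterns / ",
      x$total_columns, " columns; ",
      sprintf("%.2f%%", 100 * x$undetermined_fraction),
      " undetermined characters or gaps\n", sep = "")
  invisible(x)
}
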