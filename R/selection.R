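#' Remove low-coverage loci
#'
#' A locus is removed when it contains sequences for 50% or fewer of all
#' taxa, i.e. when its sequence count is `<= floor(total_taxa / 2)`; with 86
#' taxa a 43-sequence gene is removed and a 44-sequence gene kept.
#'
#' @param alignments List of [gene_alignment()] objects.
#' @param total_taxa Total number of taxa in the study.
#' @return A list with elements `kept` and `removed` (lists of alignments).
#' @export
coverage_filter <- function(alignments, total_taxa) {
  stopifnot(is.numeric(total_taxa), total_taxa >= 1)
  counts <- vapply(alignments, function(a) length(a$taxa), 1L)
  removed <- counts <= floor(total_taxa / 2)
  list(kept = alignments[!removed], removed = alignments[removed])
}

#' Trimming parameters for conserved-block selection
#'
#' Parameters of the simplified conserved-block trimmer, following the
#' naming of the classic Gblocks program: `b1`/`b2` are the minimum number of
#' sequences carrying the majority residue for a column to count as
#' conserved / flank-quality, `b3` is the longest run of non-conserved
#' columns tolerated inside a block, `b4` the minimum surviving block length
#' and `b5` the gap allowance per column. The relaxed setting used for
#' phylogenomic loci is `b2 = floor(N/2) + 1`, `b4 = 5`, `b5 = "half"`.
#'
#' @param n_seq Number of sequences N in the alignment to be trimmed.
#' @param b1_conserved_min,b2_flank_min Integer thresholds, both defaulting
#'   to `floor(N/2) + 1`; `b2 >= b1` is required.
#' @param b3_max_contiguous_nonconserved Default 8.
#' @param b4_min_block Default 5 (must be >= 2).
#' @param b5_gap_allowance `"none"`, `"half"` or `"all"`.
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(n_seq,
                        b1_conserved_min = floor(n_seq / 2) + 1,
                        b2_flank_min = floor(n_seq / 2) + 1,
                        b3_max_contiguous_nonconserved = 8L,
                        b4_min_block = 5L,
                        b5_gap_allowance = c("half", "none", "all")) {
  b5_gap_allowance <- match.arg(b5_gap_allowance)
  if (b2_flank_min < b1_conserved_min)
    stop("b2_flank_min must be >= b1_conserved_min")
  if (b4_min_block < 2) stop("b4_min_block must be >= 2")
  structure(list(n_seq = as.integer(n_seq),
                 b1 = as.integer(b1_conserved_min),
                 b2 = as.integer(b2_flank_min),
                 b3 = as.integer(b3_max_contiguous_nonconserved),
                 b4 = as.integer(b4_min_block),
                 b5 = b5_gap_allowance),
            class = "trim_params")
}

GAP_CHARS <- c("-", "?")

#' Trim ambiguously aligned regions
#'
#' Deterministic, simplified conserved-block trimmer. Columns are processed
#' in four stages: (1) columns whose gap fraction exceeds the `b5` allowance
#' are removed (`"none"`: any gap; `"half"`: more than 50% gaps; `"all"`: no
#' gap-based removal); (2) each surviving column is classified conserved if
#' its most frequent non-gap residue occurs in at least `b1` sequences;
#' (3) runs of more than `b3` contiguous non-conserved columns are removed;
#' (4) the remaining blocks are trimmed at both ends to start and end at
#' columns whose majority-residue count reaches `b2`, and blocks shorter
#' than `b4` are dropped. The result may have zero columns.
#'
#' @param aln A [gene_alignment()].
#' @param params A [trim_params()]; defaults to the relaxed setting for this
#'   alignment's sequence count.
#' @return The trimmed [gene_alignment()]; the retained original column
#'   indices are in `attr(, "retained_columns")` and their 1-based ranges in
#'   `attr(, "retained_ranges")`.
#' @export
trim_blocks <- function(aln, params = trim_params(length(aln$taxa))) {
  stopifnot(inherits(aln, "gene_alignment"), inherits(params, "trim_params"))
  m <- aln_matrix(aln)
  N <- nrow(m); L <- ncol(m)
  if (L == 0) return(aln)
  gap_count <- colSums(matrix(m %in% GAP_CHARS, N, L))
  keep <- switch(params$b5,
                 none = gap_count == 0,
                 half = gap_count <= N / 2,
                 all = rep(TRUE, L))
  maj <- integer(L)
  for (j in which(keep)) {
    col <- m[, j]
    col <- col[!(col %in% GAP_CHARS)]
    maj[j] <- if (length(col)) max(tabulate(factor(col, levels = unique(col))))
              else 0L
  }
  conserved <- keep & maj >= params$b1
  # remove long runs of non-conserved columns (contiguity among survivors)
  surv <- which(keep)
  if (length(surv)) {
    r <- rle(conserved[surv])
    drop_run <- rep(!r$values & r$lengths > params$b3, r$lengths)
    keep[surv[drop_run]] <- FALSE
  }
  # flank-trim each remaining block to b2-quality ends, enforce b4
  surv <- which(keep)
  if (length(surv)) {
    block_id <- cumsum(c(1L, diff(surv) != 1L))
    for (b in split(surv, block_id)) {
      good <- maj[b] >= params$b2
      if (!any(good)) { keep[b] <- FALSE; next }
      lo <- min(which(good)); hi <- max(which(good))
      keep[b[seq_along(b) < lo | seq_along(b) > hi]] <- FALSE
      kept_b <- b[lo:hi]
      if (length(kept_b) < params$b4) keep[kept_b] <- FALSE
    }
  }
  retained <- which(keep)
  out <- matrix_to_alignment(m[, retained, drop = FALSE], aln$locus_id)
  attr(out, "retained_columns") <- retained
  attr(out, "retained_ranges") <- column_ranges(retained)
  out
}

column_ranges <- function(idx) {
  if (!length(idx)) return(tibble::tibble(start = integer(0), end = integer(0)))
  tibble::tibble(start = idx[c(TRUE, diff(idx) != 1L)],
                 end = idx[c(diff(idx) != 1L, TRUE)])
}

#' Gene-count grid of an incremental concatenation design
#'
#' The gene counts scored by [selection_curve()]:
#' `start, start + step, ..., stop`, i.e.
#' `floor((stop - start) / step) + 1` points. Ten to 340 genes in steps of
#' ten, for instance, gives 34 multigene supermatrices.
#'
#' @param start,step,stop Increment grid (`step >= 1`, `start <= stop`).
#' @return Integer vector of gene counts.
#' @export
selection_grid <- function(start, step, stop) {
  stopifnot(step >= 1, start >= 1, start <= stop)
  seq.int(as.integer(start), as.integer(stop), by = as.integer(step))
}

#' Score incrementally concatenated locus sets by average bootstrap support
#'
#' The headline selection procedure: for `n = start, start + step, ..., stop`
#' the first `n` loci of the slowest-first ranking are concatenated, an ML
#' tree with bootstrap supports is inferred for the supermatrix
#' ([ml_tree_search()] + [bootstrap_support()], GTR+Gamma re-estimated per
#' increment), and the average internal-edge bootstrap value is recorded.
#' The locus set attaining the maximum average support (ties towards the
#' smaller set) is the selected set.
#'
#' @param ranked_loci List of [gene_alignment()] objects, already ranked
#'   slowest-first (see [rank_genes()]).
#' @param start,step,stop Increment grid; `stop` must not exceed the number
#'   of ranked loci.
#' @param n_bootstrap Bootstrap replicates per increment (default 100).
#' @param seed Master seed; the same seed governs all increments.
#' @param keep_trees Keep each increment's support-annotated best tree?
#' @return An object of class `selection_curve`: `points` (tibble with
#'   `n_genes`, `average_bootstrap`, `log_lik`), `selected_n`,
#'   `selected_loci`, `locus_ids` (full ranking), `seed`, and (optionally)
#'   `trees`.
#' @export
selection_curve <- function(ranked_loci, start = 10L, step = 10L,
                            stop = length(ranked_loci), n_bootstrap = 100L,
                            seed = 1L, keep_trees = TRUE) {
  stopifnot(length(ranked_loci) >= 1, step >= 1, start >= 1, start <= stop)
  if (stop > length(ranked_loci))
    stop("'stop' exceeds the number of ranked loci")
  ns <- selection_grid(start, step, stop)
  ids <- unname(vapply(ranked_loci, function(a) a$locus_id, ""))
  avg <- lnl <- numeric(length(ns))
  trees <- vector("list", length(ns))
  for (i in seq_along(ns)) {
    sm <- concatenate(ranked_loci[seq_len(ns[i])])
    bs <- bootstrap_support(sm, model = NULL, n_replicates = n_bootstrap,
                            seed = mix_seed(seed, 100000 + i))
    avg[i] <- average_bootstrap(bs)$average_bootstrap
    lnl[i] <- bs$log_lik
    if (keep_trees) trees[[i]] <- bs$best_tree
  }
  pts <- tibble::tibble(n_genes = ns, average_bootstrap = avg, log_lik = lnl)
  sel <- ns[which.max(avg)] # which.max takes the first maximum: smaller n
  structure(list(points = pts, selected_n = sel,
                 selected_loci = ids[seq_len(sel)], locus_ids = ids,
                 seed = as.integer(seed),
                 trees = if (keep_trees) stats::setNames(trees, ns)),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("<selection_curve> ", nrow(x$points), " points; max average bootstrap ",
      sprintf("%.2f", max(x$points$average_bootstrap)), " at ",
      x$selected_n, " genes\n", sep = "")
  invisible(x)
}

#' Select the locus set maximising average bootstrap support
#'
#' Argmax over the curve points; equal maxima resolve towards the smaller
#' gene count. Returns the selected prefix of the ranked locus order.
#'
#' @param curve A [selection_curve()] result.
#' @return Character vector of selected locus ids, with attribute `n`.
#' @export
select_best <- function(curve) {
  stopifnot(inherits(curve, "selection_curve"), nrow(curve$points) >= 1)
  i <- which.max(curve$points$average_bootstrap)
  n <- curve$points$n_genes[i]
  structure(curve$locus_ids[seq_len(n)], n = n)
}

#' Write the selection curve as TSV
#'
#' Columns `n_genes`, `average_bootstrap`, `log_lik`; byte-deterministic for
#' a fixed curve.
#'
#' @param curve A [selection_curve()] result.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "selection_curve"))
  df <- as.data.frame(curve$points)
  df$average_bootstrap <- sprintf("%.10g", df$average_bootstrap)
  df$log_lik <- sprintf("%.10g", df$log_lik)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
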