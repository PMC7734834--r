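#' Run the full rate-based locus-selection pipeline
#'
#' Chains the pipeline stages on a set of locus alignments and a calibrated
#' constraint chronogram: coverage filtering, optional conserved-block
#' trimming, per-locus strict-clock rate estimation (constraint tree pruned
#' to each locus's taxa), exclusion of extraordinarily fast rate outliers,
#' slowest-first ranking, incremental concatenation scored by average
#' bootstrap support, and argmax selection.
#'
#' @param loci List of [gene_alignment()] objects.
#' @param chronogram Calibrated [as_chronogram()] constraint tree covering
#'   all taxa.
#' @param start,step,stop Increment grid for [selection_curve()]; `stop`
#'   defaults to every ranked locus.
#' @param n_bootstrap Bootstrap replicates per increment.
#' @param seed Master seed for the whole run.
#' @param trim Apply [trim_blocks()] with relaxed defaults before rate
#'   estimation?
#' @param outlier_rule,exclude_ids Passed to [exclude_rate_outliers()].
#' @param model A [gtr_model()] for rate estimation (shape re-estimated per
#'   locus).
#' @param out_dir If non-`NULL`, write the standard outputs there: rates
#'   TSV, curve TSV, selected-locus list, selected supermatrix FASTA +
#'   partition table, and the selected best tree (Newick).
#' @return A list of class `locus_selection`: `rates` (ranked records),
#'   `excluded` (outlier records), `curve` (a [selection_curve()]),
#'   `selected` (locus ids), `supermatrix` (of the selected set) and
#'   `tree` (its support-annotated best tree).
#' @export
run_locus_selection <- function(loci, chronogram, start = 10L, step = 10L,
                                stop = NULL, n_bootstrap = 100L, seed = 1L,
                                trim = FALSE,
                                outlier_rule = c("mad", "explicit"),
                                exclude_ids = NULL,
                                model = gtr_model(), out_dir = NULL) {
  outlier_rule <- match.arg(outlier_rule)
  total_taxa <- length(chronogram$tip.label)
  flt <- coverage_filter(loci, total_taxa)
  kept <- flt$kept
  if (!length(kept)) stop("no loci pass the coverage filter")
  if (trim) kept <- lapply(kept, trim_blocks)
  rates <- estimate_clock_rates(kept, chronogram, model)
  out <- exclude_rate_outliers(rates, rule = outlier_rule,
                               exclude_ids = exclude_ids)
  # saturated loci may sit on the rate bound (flagged unconverged); they are
  # still rankable — they simply rank last
  ranked <- rank_genes(out$kept, allow_unconverged = TRUE)
  by_id <- stats::setNames(kept, vapply(kept, function(a) a$locus_id, ""))
  ranked_loci <- by_id[ranked$locus_id]
  if (is.null(stop)) stop <- length(ranked_loci)
  curve <- selection_curve(ranked_loci, start = start, step = step,
                           stop = stop, n_bootstrap = n_bootstrap,
                           seed = seed)
  selected <- select_best(curve)
  sm <- concatenate(ranked_loci[selected])
  tree <- curve$trees[[as.character(attr(selected, "n"))]]
  res <- structure(list(rates = ranked, excluded = out$excluded,
                        curve = curve, selected = selected,
                        supermatrix = sm, tree = tree, seed = seed),
                   class = "locus_selection")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rates_table(ranked, file.path(out_dir, "rates.tsv"))
    write_curve(curve, file.path(out_dir, "curve.tsv"))
    writeLines(selected, file.path(out_dir, "selected_loci.txt"))
    write_fasta(sm, file.path(out_dir, "selected_supermatrix.fasta"))
    write_partitions(sm, file.path(out_dir, "selected_partitions.txt"))
    writeLines(write_newick(tree), file.path(out_dir, "selected_tree.nwk"))
  }
  res
}

#' @export
print.locus_selection <- function(x, ...) {
  cat("<locus_selection> ", length(x$curve$locus_ids), " ranked loci; ",
      nrow(x$excluded), " rate outlier(s) excluded; selected ",
      attr(x$selected, "n"), " loci (max average bootstrap ",
      sprintf("%.2f", max(x$curve$points$average_bootstrap)), ")\n", sep = "")
  invisible(x)
}
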