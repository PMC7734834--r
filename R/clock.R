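#' Estimate a per-locus absolute substitution rate under a strict clock
#'
#' Fits a single substitution rate (substitutions/site/Myr) for one locus on
#' a calibrated chronogram: the expected length of every branch is
#' `rate x (age(parent) - age(child))`, node ages are held fixed at the
#' chronogram's values, the topology is fixed, and the scalar rate is
#' maximised by bounded 1-D likelihood search. Because ages are fixed, the
#' estimates across loci share one time scale and are directly comparable —
#' which is what the downstream slowest-first ranking consumes. The gamma
#' shape can optionally be re-estimated per locus by a grid-then-refine
#' search on the fixed tree.
#'
#' @param aln A [gene_alignment()] whose taxa equal the chronogram's tips
#'   (prune first with [prune_to_taxa()]); at least 4 taxa.
#' @param chronogram A [as_chronogram()] tree with ages in Myr.
#' @param model A [gtr_model()]; its gamma shape is the starting value when
#'   `optimize_shape = TRUE`.
#' @param rate_bounds Search interval for the rate (subs/site/Myr).
#' @param optimize_shape Re-estimate the gamma shape for this locus?
#' @return A one-row tibble (the per-locus rate record) with columns
#'   `locus_id`, `n_taxa`, `rate`, `gamma_shape`, `log_lik`, `converged`.
#' @export
estimate_clock_rate <- function(aln, chronogram, model = gtr_model(),
                                rate_bounds = c(0, 10),
                                optimize_shape = TRUE) {
  stopifnot(inherits(aln, "gene_alignment"), inherits(model, "gtr_model"))
  if (!inherits(chronogram, "chronogram"))
    stop("'chronogram' must be an ultrametric chronogram (see as_chronogram)")
  if (length(aln$taxa) < 4) stop("need at least 4 taxa for a rate estimate")
  check_taxa_match(chronogram, aln$taxa)
  tree_po <- stats::reorder(chronogram, "postorder")
  ages <- node_ages(chronogram)
  durations <- ages[tree_po$edge[, 1]] - ages[tree_po$edge[, 2]]
  kern <- lik_kernel(aln_matrix(aln))
  eig <- rate_matrix_eigen(build_rate_matrix(model), model$base_freqs)
  obj <- function(rate, shape) {
    m <- model
    m$gamma_shape <- shape
    kernel_loglik(kern, tree_po, rate * durations, m, eig)
  }
  # The likelihood surface is flat once every branch is saturated, so a bare
  # golden-section search over the full rate interval can stall on the
  # plateau. Probe log-spaced rates first and optimise inside the bracket
  # around the best probe.
  probes <- sort(unique(pmin(pmax(
    c(rate_bounds[1], 10^seq(-6, 1, by = 0.5), rate_bounds[2]),
    rate_bounds[1]), rate_bounds[2])))
  best_rate_for <- function(shape, tol) {
    ll <- vapply(probes, obj, 0, shape = shape)
    i <- which.max(ll)
    lo <- probes[max(1, i - 1)]
    hi <- probes[min(length(probes), i + 1)]
    opt <- stats::optimize(function(r) -obj(r, shape),
                           interval = c(lo, hi), tol = tol)
    if (-opt$objective >= ll[i]) list(rate = opt$minimum, loglik = -opt$objective)
    else list(rate = probes[i], loglik = ll[i])
  }
  shape <- model$gamma_shape
  if (optimize_shape) {
    grid <- c(0.2, 0.5, 1, 2, 5)
    coarse <- lapply(grid, best_rate_for, tol = 1e-7)
    ll <- vapply(coarse, `[[`, 0, "loglik")
    i <- which.max(ll)
    lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
    ref <- stats::optimize(function(la) -best_rate_for(exp(la), 1e-7)$loglik,
                           interval = c(lo, hi), tol = 1e-3)
    shape <- exp(ref$minimum)
  }
  fine <- best_rate_for(shape, tol = 1e-12)
  converged <- fine$rate > rate_bounds[1] + 1e-10 &&
    fine$rate < rate_bounds[2] - 1e-6
  # a rate at the lower bound with identical sequences is a valid "0" fit
  if (fine$rate <= rate_bounds[1] + 1e-10) converged <- TRUE
  tibble::tibble(locus_id = aln$locus_id, n_taxa = length(aln$taxa),
                 rate = fine$rate, gamma_shape = shape,
                 log_lik = fine$loglik, converged = converged)
}

#' Estimate clock rates for a set of loci
#'
#' Convenience wrapper: prunes the calibrated constraint chronogram to each
#' locus's taxa, then runs [estimate_clock_rate()] per locus. Loci with fewer
#' than 4 taxa are skipped with a warning.
#'
#' @inheritParams estimate_clock_rate
#' @param loci List of [gene_alignment()] objects.
#' @return A tibble with one row per estimated locus.
#' @export
estimate_clock_rates <- function(loci, chronogram, model = gtr_model(),
                                 optimize_shape = TRUE) {
  keep <- vapply(loci, function(a) length(a$taxa) >= 4, TRUE)
  if (any(!keep))
    warning(sum(!keep), " locus/loci with < 4 taxa skipped")
  rows <- lapply(loci[keep], function(a) {
    chr <- prune_to_taxa(chronogram, a$taxa)
    estimate_clock_rate(a, chr, model, optimize_shape = optimize_shape)
  })
  dplyr::bind_rows(rows)
}

#' Rank loci from slowest to fastest
#'
#' Ascending sort on the estimated substitution rate; ties are broken by
#' `locus_id` (lexicographic), so the ranking is total and reproducible.
#'
#' @param records Tibble of rate records (from [estimate_clock_rates()]).
#' @param allow_unconverged Keep records whose optimisation did not converge?
#'   By default their presence is an error.
#' @return The records tibble, reordered.
#' @export
rank_genes <- function(records, allow_unconverged = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("locus_id", "rate", "converged") %in% names(records)))
  if (!allow_unconverged && any(!records$converged))
    stop("unconverged rate record(s): ",
         paste(records$locus_id[!records$converged], collapse = ", "))
  ord <- order(records$rate, records$locus_id, method = "radix")
  records[ord, , drop = FALSE]
}

#' Exclude extraordinarily fast loci
#'
#' Removes rate outliers before ranking-based selection. The default
#' statistical rule excludes records with
#' `rate > median(rate) + k * mad(rate)` (high side only, `k = 5`); the
#' explicit-list mode reproduces a manual curation decision instead.
#'
#' @param records Tibble of rate records.
#' @param rule `"mad"` (default) or `"explicit"`.
#' @param exclude_ids Locus ids to drop when `rule = "explicit"`.
#' @param k Multiplier on the median absolute deviation
#'   ([stats::mad()], with its usual consistency constant).
#' @return A list with tibbles `kept` and `excluded`.
#' @export
exclude_rate_outliers <- function(records, rule = c("mad", "explicit"),
                                  exclude_ids = NULL, k = 5) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(records), "rate" %in% names(records))
  if (rule == "explicit") {
    out <- records$locus_id %in% exclude_ids
  } else {
    if (nrow(records) < 5)
      stop("need at least 5 records for the statistical outlier rule")
    cutoff <- stats::median(records$rate) + k * stats::mad(records$rate)
    out <- records$rate > cutoff
  }
  list(kept = records[!out, , drop = FALSE],
       excluded = records[out, , drop = FALSE])
}

#' Write a per-locus rates table
#'
#' Tab-separated columns `locus_id`, `n_taxa`, `rate` (subs/site/Myr),
#' `gamma_shape`, `log_lik`, `converged`.
#'
#' @param records Tibble of rate records.
#' @param path Output path.
#' @export
write_rates_table <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
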