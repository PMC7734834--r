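#' Gene-recovery accounting report
#'
#' Summarises how much of each reference gene was recovered per taxon and
#' extraction method, mirroring the bookkeeping done on target-capture
#' assemblies: per-(taxon, locus, method) percent recovered (capped at 100),
#' per-taxon totals, per-method mean and standard deviation of the totals
#' (sample SD, n-1 denominator), and the loci recovered by only half of
#' their reference length or less in a majority of taxa.
#'
#' @param recovered Data frame with columns `taxon`, `locus`, `method`,
#'   `recovered_length` (one row per taxon x locus x method; absent rows
#'   count as length 0).
#' @param reference Data frame with columns `locus`, `reference_length`
#'   (all lengths > 0), or a named numeric vector.
#' @return An object of class `recovery_report`: tibbles `percent` (long,
#'   one row per taxon x locus x method), `taxon_totals`, `method_summary`,
#'   and `poorly_recovered` (per method, the loci at <= 50% in a majority of
#'   taxa).
#' @export
recovery_report <- function(recovered, reference) {
  if (!is.data.frame(reference))
    reference <- tibble::tibble(locus = names(reference),
                                reference_length = as.numeric(reference))
  stopifnot(all(c("taxon", "locus", "method", "recovered_length") %in%
                  names(recovered)),
            all(c("locus", "reference_length") %in% names(reference)))
  if (any(reference$reference_length <= 0))
    stop("reference lengths must be positive")
  unknown <- setdiff(unique(recovered$locus), reference$locus)
  if (length(unknown))
    stop("locus/loci absent from reference: ", paste(unknown, collapse = ", "))
  grid <- tidyr::expand_grid(taxon = sort(unique(recovered$taxon)),
                             locus = sort(unique(reference$locus)),
                             method = sort(unique(recovered$method)))
  pct <- grid |>
    dplyr::left_join(recovered, by = c("taxon", "locus", "method")) |>
    dplyr::left_join(reference, by = "locus") |>
    dplyr::mutate(
      recovered_length = dplyr::coalesce(.data$recovered_length, 0),
      percent = pmin(100, 100 * .data$recovered_length /
                       .data$reference_length))
  taxon_totals <- pct |>
    dplyr::group_by(.data$method, .data$taxon) |>
    dplyr::summarise(total_recovered = sum(.data$recovered_length),
                     .groups = "drop")
  method_summary <- taxon_totals |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_total = mean(.data$total_recovered),
                     sd_total = stats::sd(.data$total_recovered),
                     n_taxa = dplyr::n(), .groups = "drop")
  poorly <- pct |>
    dplyr::group_by(.data$method, .data$locus) |>
    dplyr::summarise(frac_half_or_less = mean(.data$percent <= 50),
                     .groups = "drop") |>
    dplyr::filter(.data$frac_half_or_less > 0.5)
  structure(list(percent = pct, taxon_totals = taxon_totals,
                 method_summary = method_summary,
                 poorly_recovered = poorly),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", dplyr::n_distinct(x$percent$taxon), " taxa x ",
      dplyr::n_distinct(x$percent$locus), " loci x ",
      dplyr::n_distinct(x$percent$method), " method(s)\n", sep = "")
  print(x$method_summary)
  invisible(x)
}

#' Write the percent-recovery heatmap matrix
#'
#' One TSV per call: rows are taxa, columns loci, cells percent recovered,
#' for a single method.
#'
#' @param report A [recovery_report()].
#' @param method Which method's matrix to write.
#' @param path Output path.
#' @export
write_recovery_matrix <- function(report, method, path) {
  stopifnot(inherits(report, "recovery_report"))
  wide <- report$percent |>
    dplyr::filter(.data$method == !!method) |>
    dplyr::select("taxon", "locus", "percent") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "percent")
  utils::write.table(as.data.frame(wide), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
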