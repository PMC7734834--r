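make_gene <- function(id, n) {
  gene_alignment(setNames(rep("ACGT", n), sprintf("t%02d", seq_len(n))), id)
}

test_that("coverage filter removes loci at 50% of taxa or fewer", {
  genes <- list(make_gene("at43", 43), make_gene("at44", 44),
                make_gene("full", 86))
  flt <- coverage_filter(genes, total_taxa = 86)
  kept_ids <- vapply(flt$kept, function(a) a$locus_id, "")
  expect_setequal(kept_ids, c("at44", "full"))
  expect_equal(vapply(flt$removed, function(a) a$locus_id, ""), "at43")

  empty <- gene_alignment(setNames(character(0), character(0)), "none")
  expect_equal(length(coverage_filter(list(empty), 10)$removed), 1L)
})

test_that("coverage filter is monotone in the number of sequences", {
  set.seed(8)
  for (i in 1:20) {
    total <- sample(5:30, 1)
    k <- sample(0:total, 1)
    g <- make_gene("g", max(k, 0))
    kept_now <- length(coverage_filter(list(g), total)$kept) == 1
    if (k < total) {
      g2 <- make_gene("g", k + 1)
      kept_more <- length(coverage_filter(list(g2), total)$kept) == 1
      expect_true(!kept_now || kept_more)
    }
  }
})

test_that("trim parameters enforce their invariants", {
  p <- trim_params(10)
  expect_equal(p$b1, 6L); expect_equal(p$b2, 6L)
  expect_equal(p$b4, 5L); expect_equal(p$b5, "half")
  expect_error(trim_params(10, b1_conserved_min = 8, b2_flank_min = 6), "b2")
  expect_error(trim_params(10, b4_min_block = 1), "b4")
})

test_that("a fully conserved gap-free alignment is untouched", {
  aln <- gene_alignment(setNames(rep(strrep("ACGTT", 4), 6),
                                 paste0("t", 1:6)))
  out <- trim_blocks(aln)
  expect_identical(out$seqs, aln$seqs)
  expect_equal(attr(out, "retained_columns"), 1:20)
})

test_that("majority-gap columns are removed under the half allowance", {
  # column 3 has gaps in 3/4 sequences; all other columns fully conserved
  base <- strrep("A", 12)
  seqs <- c(t1 = base,
            t2 = sub("^(..).", "\\1-", base),
            t3 = sub("^(..).", "\\1-", base),
            t4 = sub("^(..).", "\\1-", base))
  out <- trim_blocks(gene_alignment(seqs), trim_params(4, b4_min_block = 2))
  expect_false(3L %in% attr(out, "retained_columns"))
  expect_equal(out$length, 11L)
})

test_that("a short conserved island inside noise is dropped by b4", {
  set.seed(12)
  n <- 8
  noise <- function(l) replicate(l, paste0(sample(c("A", "C", "G", "T")), collapse = ""))
  # columns: 12 noisy (each residue at most 2/8 < b1), 4 conserved, 12 noisy
  noisy_cols <- function(l) vapply(seq_len(l), function(i)
    paste0(sample(rep(c("A", "C", "G", "T"), 2)), collapse = ""), "")
  island <- vapply(1:4, function(i) strrep("G", n), "")
  cols <- c(noisy_cols(12), island, noisy_cols(12))
  m <- do.call(cbind, strsplit(cols, ""))
  rownames(m) <- paste0("t", 1:n)
  out <- trim_blocks(gene_alignment(m), trim_params(n, b4_min_block = 5))
  expect_equal(out$length, 0L)

  # with b4 = 4 and a tolerant b3 the island survives as a block
  out2 <- trim_blocks(gene_alignment(m),
                      trim_params(n, b3_max_contiguous_nonconserved = 20L,
                                  b4_min_block = 4L))
  expect_equal(attr(out2, "retained_columns"), 13:16)
  expect_equal(attr(out2, "retained_ranges")$start, 13L)
  expect_equal(attr(out2, "retained_ranges")$end, 16L)
})

test_that("the selection grid counts increments as floor((stop-start)/step)+1", {
  expect_length(selection_grid(10, 10, 340), 34L)
  expect_equal(selection_grid(5, 5, 50), seq(5, 50, 5))
  expect_equal(selection_grid(7, 7, 7), 7L)
  for (i in 1:10) {
    set.seed(i)
    start <- sample(1:20, 1); step <- sample(1:10, 1)
    stop <- start + sample(0:50, 1)
    expect_length(selection_grid(start, step, stop),
                  floor((stop - start) / step) + 1)
  }
})

fake_curve <- function(ns, avg) {
  structure(list(points = tibble::tibble(n_genes = ns,
                                         average_bootstrap = avg,
                                         log_lik = -seq_along(ns)),
                 selected_n = ns[which.max(avg)],
                 selected_loci = sprintf("L%03d", seq_len(ns[which.max(avg)])),
                 locus_ids = sprintf("L%03d", seq_len(max(ns))),
                 seed = 1L, trees = NULL),
            class = "selection_curve")
}

test_that("argmax selection prefers smaller gene counts on ties", {
  inc <- fake_curve(c(10, 20, 30), c(90, 95, 99))
  sel <- select_best(inc)
  expect_equal(attr(sel, "n"), 30L)
  expect_length(sel, 30L)

  tie <- fake_curve(c(50, 80), c(99.1, 99.1))
  expect_equal(attr(select_best(tie), "n"), 50L)

  expect_true(all(select_best(tie) == sprintf("L%03d", 1:50)))
})

test_that("a small selection curve runs end to end deterministically", {
  cfg <- simulation_config(n_taxa = 8, n_slow_loci = 4, n_fast_loci = 2,
                           locus_length_range = c(120, 200),
                           missing_taxon_fraction = 0, seed = 77)
  ds <- simulate_dataset(cfg)
  curve <- selection_curve(ds$loci, start = 2, step = 2, stop = 6,
                           n_bootstrap = 4, seed = 11)
  expect_equal(curve$points$n_genes, c(2L, 4L, 6L))
  expect_true(all(curve$points$average_bootstrap >= 0 &
                    curve$points$average_bootstrap <= 100))
  expect_true(curve$selected_n %in% curve$points$n_genes)
  expect_identical(curve$selected_loci,
                   curve$locus_ids[seq_len(curve$selected_n)])
  # the selected set is always a prefix of the ranked order
  sel <- select_best(curve)
  expect_identical(as.character(sel),
                   curve$locus_ids[seq_along(sel)])

  curve2 <- selection_curve(ds$loci, start = 2, step = 2, stop = 6,
                            n_bootstrap = 4, seed = 11)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_curve(curve, p1); write_curve(curve2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(selection_curve(ds$loci, start = 2, step = 2, stop = 9),
               "exceeds")
})

test_that("selection curves tidy, glance and plot", {
  cv <- fake_curve(c(10, 20), c(95, 99))
  td <- tidy(cv)
  expect_equal(td$selected, c(FALSE, TRUE))
  gl <- glance(cv)
  expect_equal(gl$selected_n, 20L)
  expect_equal(gl$max_average_bootstrap, 99)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
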