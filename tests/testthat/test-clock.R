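test_that("identical sequences give a rate at the lower bound", {
  chrono <- simulate_chronogram(4, 108, seed = 1)
  aln <- gene_alignment(setNames(rep(strrep("ACGT", 50), 4),
                                 chrono$tip.label))
  rec <- estimate_clock_rate(aln, chrono, gtr_model(), optimize_shape = FALSE)
  expect_lt(rec$rate, 1e-6)
  expect_true(rec$converged)
})

test_that("the strict-clock estimator recovers a simulated rate", {
  m <- simulation_config(seed = 1)$model
  chrono <- simulate_chronogram(10, 108, seed = 61)
  aln <- simulate_locus(chrono, 0.002, m, 2000, seed = 62)
  rec <- estimate_clock_rate(aln, chrono, m)
  expect_lt(abs(rec$rate - 0.002) / 0.002, 0.15)
  expect_true(rec$converged)
  expect_equal(rec$n_taxa, 10L)
})

test_that("doubling all node ages exactly halves the estimated rate", {
  m <- simulation_config(seed = 1)$model
  chrono <- simulate_chronogram(8, 108, seed = 63)
  aln <- simulate_locus(chrono, 0.0015, m, 1000, seed = 64)
  r1 <- estimate_clock_rate(aln, chrono, m, optimize_shape = FALSE)
  doubled <- chrono
  doubled$edge.length <- doubled$edge.length * 2
  doubled <- as_chronogram(doubled)
  r2 <- estimate_clock_rate(aln, doubled, m, optimize_shape = FALSE)
  expect_equal(r2$rate, r1$rate / 2, tolerance = 1e-6)
  expect_equal(r2$log_lik, r1$log_lik, tolerance = 1e-6)
})

test_that("rate estimates ignore taxon order and column order", {
  m <- simulation_config(seed = 1)$model
  chrono <- simulate_chronogram(6, 108, seed = 65)
  aln <- simulate_locus(chrono, 0.003, m, 500, seed = 66)
  r0 <- estimate_clock_rate(aln, chrono, m, optimize_shape = FALSE)
  perm <- gene_alignment(aln$seqs[sample(seq_along(aln$taxa))], aln$locus_id)
  set.seed(67)
  cols <- sample(aln$length)
  mm <- do.call(rbind, strsplit(aln$seqs, ""))[, cols]
  rownames(mm) <- aln$taxa
  shuf <- gene_alignment(mm, aln$locus_id)
  expect_equal(estimate_clock_rate(perm, chrono, m,
                                   optimize_shape = FALSE)$rate,
               r0$rate, tolerance = 1e-9)
  expect_equal(estimate_clock_rate(shuf, chrono, m,
                                   optimize_shape = FALSE)$rate,
               r0$rate, tolerance = 1e-9)
})

test_that("pruning before estimation equals estimation on the pruned taxa", {
  m <- simulation_config(seed = 1)$model
  chrono <- simulate_chronogram(8, 108, seed = 68)
  aln <- simulate_locus(chrono, 0.002, m, 400, seed = 69)
  keep <- chrono$tip.label[1:5]
  sub <- gene_alignment(aln$seqs[keep], aln$locus_id)
  pruned <- prune_to_taxa(chrono, keep)
  direct <- estimate_clock_rate(sub, pruned, m, optimize_shape = FALSE)
  via_wrapper <- estimate_clock_rates(list(sub), chrono, m,
                                      optimize_shape = FALSE)
  expect_equal(via_wrapper$rate, direct$rate, tolerance = 1e-12)
})

test_that("validation rejects bad inputs", {
  chrono <- simulate_chronogram(5, 108, seed = 70)
  small <- gene_alignment(setNames(rep("ACGT", 3), chrono$tip.label[1:3]))
  expect_error(estimate_clock_rate(small, prune_to_taxa(chrono, chrono$tip.label[1:3]),
                                   gtr_model()), "4 taxa")
  set.seed(71)
  nonclock <- ape::rtree(5)
  aln <- rand_alignment(5, 20, seed = 72)
  expect_error(estimate_clock_rate(aln, nonclock, gtr_model()), "chronogram")
})

test_that("ranking is ascending with lexicographic tie-breaks", {
  rec <- tibble::tibble(locus_id = c("g2", "g1", "g3"),
                        rate = c(0.5, 0.5, 0.1),
                        converged = TRUE)
  expect_equal(rank_genes(rec)$locus_id, c("g3", "g1", "g2"))
  sorted <- tibble::tibble(locus_id = paste0("g", 1:4),
                           rate = c(1, 2, 3, 4), converged = TRUE)
  expect_identical(rank_genes(sorted), sorted)
  set.seed(73)
  big <- tibble::tibble(locus_id = sprintf("L%03d", 1:100),
                        rate = runif(100), converged = TRUE)
  expect_equal(rank_genes(big)$rate, sort(big$rate))
  bad <- rec; bad$converged[2] <- FALSE
  expect_error(rank_genes(bad), "g1")
  expect_equal(nrow(rank_genes(bad, allow_unconverged = TRUE)), 3L)
})

test_that("outlier exclusion removes planted fast genes and honours lists", {
  equal <- tibble::tibble(locus_id = paste0("g", 1:6), rate = rep(0.001, 6),
                          converged = TRUE)
  expect_equal(nrow(exclude_rate_outliers(equal)$excluded), 0L)

  set.seed(74)
  rates <- c(rnorm(48, 0.001, 0.0001), 0.05, 0.06)
  recs <- tibble::tibble(locus_id = sprintf("g%02d", 1:50), rate = rates,
                         converged = TRUE)
  out <- exclude_rate_outliers(recs)
  expect_setequal(out$excluded$locus_id, c("g49", "g50"))
  expect_equal(nrow(out$kept), 48L)

  expl <- exclude_rate_outliers(recs, rule = "explicit",
                                exclude_ids = c("g01", "g07"))
  expect_setequal(expl$excluded$locus_id, c("g01", "g07"))
  expect_error(exclude_rate_outliers(recs[1:3, ]), "at least 5")
})

test_that("rates tables round-trip through TSV", {
  rec <- tibble::tibble(locus_id = c("a", "b"), n_taxa = c(5L, 6L),
                        rate = c(0.0012345678, 0.05), gamma_shape = c(1, 2),
                        log_lik = c(-100.5, -200.25), converged = c(TRUE, TRUE))
  path <- withr::local_tempfile()
  write_rates_table(rec, path)
  back <- utils::read.delim(path)
  expect_equal(back$rate, rec$rate, tolerance = 1e-9)
  expect_equal(back$locus_id, rec$locus_id)
})
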