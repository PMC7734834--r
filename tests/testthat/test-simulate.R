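test_that("simulated chronograms are ultrametric with the requested calibration", {
  two <- simulate_chronogram(2, 108, seed = 1)
  expect_equal(length(two$tip.label), 2L)
  expect_equal(unname(ape::cophenetic.phylo(two)[1, 2]), 216, tolerance = 1e-9)
  for (s in 1:5) {
    chr <- simulate_chronogram(sample(4:20, 1), 108, seed = s)
    expect_s3_class(chr, "chronogram")
    expect_equal(root_age(chr), 108, tolerance = 1e-9)
  }
})

test_that("Yule node ages match an independent forward sampler (KS)", {
  set.seed(202)
  mine <- unlist(lapply(1:200, function(i) {
    chr <- simulate_chronogram(10, 1, seed = mix_seed(202, i))
    ages <- node_ages(chr)
    inner <- ages[(11:19)[-1]] # non-root internal nodes
    inner / root_age(chr)
  }))
  indep <- unlist(replicate(200, fwd_yule_ages(10), simplify = FALSE))
  expect_gt(stats::ks.test(mine, indep)$p.value, 0.01)
})

test_that("zero rate copies the root sequence everywhere; seeds reproduce", {
  chr <- simulate_chronogram(6, 108, seed = 3)
  frozen <- simulate_locus(chr, 0, gtr_model(), 200, seed = 4)
  expect_equal(length(unique(unname(frozen$seqs))), 1L)
  a <- simulate_locus(chr, 0.01, gtr_model(), 300, seed = 5)
  b <- simulate_locus(chr, 0.01, gtr_model(), 300, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_locus(chr, 0.01, gtr_model(), 300, seed = 6)))
})

test_that("two-taxon JC divergence matches the closed form", {
  chr <- simulate_chronogram(2, 108, seed = 7)
  r <- 0.001
  aln <- simulate_locus(chr, r, gtr_model(n_categories = 1L), 10000, seed = 8)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  p_obs <- mean(m[1, ] != m[2, ])
  d <- 2 * r * 108
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("saturated loci approach stationary coincidence identity", {
  # taxa separated by the full 2 x 108 Myr path: at the fast-class rate
  # every gamma category has been fully randomised
  cfg <- simulation_config(seed = 1)
  chr <- simulate_chronogram(8, 108, seed = 9)
  aln <- simulate_locus(chr, 0.05, cfg$model, 2000, seed = 10)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  d <- ape::cophenetic.phylo(chr)
  pairs <- utils::combn(nrow(m), 2)
  deep <- pairs[, apply(pairs, 2, function(p)
    d[aln$taxa[p[1]], aln$taxa[p[2]]] > 215), drop = FALSE]
  expect_gt(ncol(deep), 3)
  ident <- mean(apply(deep, 2, function(p) mean(m[p[1], ] == m[p[2], ])))
  expect_lt(abs(ident - sum(cfg$model$base_freqs^2)), 0.02)
})

test_that("dataset generation honours the configuration and truth record", {
  cfg <- simulation_config(n_taxa = 10, n_slow_loci = 7, n_fast_loci = 5,
                           locus_length_range = c(80, 150),
                           conflict_fraction = 0.6, seed = 11)
  ds <- simulate_dataset(cfg)
  expect_length(ds$loci, 12L)
  expect_equal(sum(ds$truth$class == "slow"), 7L)
  expect_equal(sum(ds$truth$conflict), 3L) # round(0.6 * 5)
  expect_true(all(ds$truth$true_rate[ds$truth$class == "slow"] >=
                    cfg$slow_rate_range[1] - 1e-12))
  expect_true(all(ds$truth$true_rate[ds$truth$class == "fast"] <=
                    cfg$fast_rate_range[2] + 1e-12))
  expect_true(all(ds$truth$length >= 80 & ds$truth$length <= 150))
  expect_true(all(vapply(ds$loci, function(a) length(a$taxa), 1L) >= 4))
  # conflicting loci have a different generating topology
  for (id in names(ds$gene_trees))
    expect_gt(rf_distance(ds$gene_trees[[id]], ds$chronogram), 0L)
})

test_that("per-locus taxon dropout matches the configured rate", {
  cfg <- simulation_config(n_taxa = 20, n_slow_loci = 100, n_fast_loci = 0,
                           locus_length_range = c(10, 12),
                           missing_taxon_fraction = 0.1, seed = 12)
  ds <- simulate_dataset(cfg)
  kept <- vapply(ds$loci, function(a) length(a$taxa), 1L)
  p_obs <- 1 - mean(kept) / 20
  se <- sqrt(0.1 * 0.9 / (20 * 100))
  expect_lt(abs(p_obs - 0.1), 3 * se)
})

test_that("datasets write deterministically to disk", {
  cfg <- simulation_config(n_taxa = 6, n_slow_loci = 2, n_fast_loci = 2,
                           locus_length_range = c(30, 50), seed = 13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 4)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  tt <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(tt), 4L)
})

test_that("rate recovery across simulated loci correlates with truth", {
  cfg <- simulation_config(n_taxa = 8, n_slow_loci = 10, n_fast_loci = 0,
                           slow_rate_range = c(5e-4, 5e-3),
                           locus_length_range = c(400, 600),
                           missing_taxon_fraction = 0, seed = 14)
  ds <- simulate_dataset(cfg)
  rates <- estimate_clock_rates(ds$loci, ds$chronogram, cfg$model,
                                optimize_shape = FALSE)
  r <- stats::cor(log(rates$rate), log(ds$truth$true_rate))
  expect_gt(r, 0.9)
})
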