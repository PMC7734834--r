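test_that("zero-distance limit: identical sequences give sum of log frequencies", {
  m <- rand_model(3)
  seqs <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  aln <- gene_alignment(seqs)
  tr <- read_newick("((a:0,b:0):0,c:0);")
  ll <- log_likelihood(tr, aln, m)
  states <- strsplit(seqs[[1]], "")[[1]]
  expect_equal(ll, sum(log(m$base_freqs[states])), tolerance = 1e-10)
})

test_that("pruning equals brute-force state enumeration on 4-taxon trees", {
  for (s in 1:3) {
    m <- rand_model(20 + s, k = 2L)
    aln <- rand_alignment(4, 10, seed = 30 + s, gap_prob = 0.15)
    set.seed(40 + s)
    tr <- ape::rtree(4, tip.label = aln$taxa)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
    mine <- log_likelihood(tr, aln, m)
    oracle <- brute_force_loglik(tr, aln, m)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("duplicated columns double the log-likelihood (pattern weights)", {
  m <- rand_model(5)
  aln <- rand_alignment(5, 20, seed = 50, gap_prob = 0.1)
  set.seed(51)
  tr <- ape::rtree(5, tip.label = aln$taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  dup <- gene_alignment(setNames(paste0(aln$seqs, aln$seqs), aln$taxa))
  expect_equal(log_likelihood(tr, dup, m),
               2 * log_likelihood(tr, aln, m), tolerance = 1e-10)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  m <- rand_model(6)
  aln <- rand_alignment(6, 30, seed = 60)
  set.seed(61)
  tr <- ape::unroot(ape::rtree(6, tip.label = aln$taxa))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  base <- log_likelihood(tr, aln, m)
  for (node in unique(tr$edge[, 1])) {
    rerooted <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(log_likelihood(rerooted, aln, m), base, tolerance = 1e-9)
  }
})

test_that("likelihood agrees with an independent GTR+Gamma implementation", {
  m <- rand_model(8)
  aln <- rand_alignment(7, 120, seed = 70, gap_prob = 0.05)
  set.seed(71)
  tr <- ape::unroot(ape::rtree(7, tip.label = aln$taxa))
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.4)
  dat <- phangorn::phyDat(do.call(rbind, strsplit(aln$seqs, "")), type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = unname(m$base_freqs),
                       Q = unname(m$exchangeabilities),
                       shape = m$gamma_shape, k = m$n_categories)
  expect_equal(log_likelihood(tr, aln, m), as.numeric(stats::logLik(fit)),
               tolerance = 1e-8)
})

test_that("per-partition models sum over partitions", {
  m1 <- rand_model(81); m2 <- rand_model(82)
  a1 <- rand_alignment(5, 15, seed = 83, locus_id = "p1")
  a2 <- rand_alignment(5, 25, seed = 84, locus_id = "p2")
  sm <- concatenate(list(a1, a2))
  set.seed(85)
  tr <- ape::rtree(5, tip.label = sm$taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  joint <- log_likelihood(tr, sm, list(p1 = m1, p2 = m2))
  expect_equal(joint,
               log_likelihood(tr, a1, m1) + log_likelihood(tr, a2, m2),
               tolerance = 1e-10)
})

test_that("taxon mismatches are reported with the symmetric difference", {
  m <- rand_model(9)
  aln <- rand_alignment(4, 10, seed = 90)
  tr <- read_newick("((s01:1,s02:1):1,(s03:1,zzz:1):1);")
  expect_error(log_likelihood(tr, aln, m), "zzz")
  expect_error(log_likelihood(tr, aln, m), "s04")
})

test_that("branch-length optimisation hits closed-form and bound cases", {
  jc <- gtr_model(n_categories = 1L)
  same <- gene_alignment(c(a = strrep("ACGT", 25), b = strrep("ACGT", 25)))
  tr <- read_newick("(a:0.1,b:0.1);")
  opt <- optimize_branch_lengths(tr, same, jc)
  expect_true(all(opt$edge.length <= 1e-6))

  # two taxa, JC: ML total distance is -3/4 log(1 - 4p/3)
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("C", 20), strrep("A", 80)) # p = 0.2
  two <- gene_alignment(c(a = s1, b = s2))
  opt2 <- optimize_branch_lengths(read_newick("(a:0.05,b:0.05);"), two, jc)
  expect_equal(sum(opt2$edge.length), -0.75 * log(1 - 4 * 0.2 / 3),
               tolerance = 1e-4)
})

test_that("branch-length optimisation converges from different starts", {
  m <- rand_model(12, k = 2L)
  chrono <- simulate_chronogram(5, 50, seed = 13)
  aln <- simulate_locus(chrono, 0.004, m, 400, seed = 14)
  tr <- ape::unroot(chrono)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  o1 <- optimize_branch_lengths(tr, aln, m)
  tr2 <- tr; tr2$edge.length <- rep(0.4, nrow(tr$edge))
  o2 <- optimize_branch_lengths(tr2, aln, m)
  expect_equal(attr(o1, "logLik"), attr(o2, "logLik"), tolerance = 1e-4)
  expect_gte(attr(o1, "logLik"), log_likelihood(tr, aln, m))
})
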