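#' Configuration for a synthetic multi-locus dataset
#'
#' Describes the statistical structure the selection pipeline assumes: a
#' known calibrated species chronogram, slow clock-like loci, fast (possibly
#' saturated) loci of which a fraction evolve on a perturbed topology
#' (emulating gene-tree conflict), per-locus locus-length variation and
#' per-locus taxon dropout. The defaults emulate the shape of a fungal
#' target-capture study: 86 taxa, ~350 loci of 300-2000 nt, a 108-Ma root,
#' slow rates of 5e-4 to 3e-3 subs/site/Myr and fast rates of 2e-2 to 1e-1
#' (deeply saturated at this time depth).
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param root_age Root calibration age in Myr.
#' @param n_slow_loci,n_fast_loci Locus counts for the two rate classes.
#' @param slow_rate_range,fast_rate_range Rate intervals (subs/site/Myr);
#'   per-locus rates are drawn log-uniformly within them.
#' @param conflict_fraction Fraction of fast loci simulated on a topology
#'   perturbed by 2 random NNI moves.
#' @param locus_length_range Locus length interval (nucleotides).
#' @param missing_taxon_fraction Per-locus, per-taxon dropout probability.
#' @param model A [gtr_model()] used for all loci.
#' @param seed Master seed; all randomness flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 86L, root_age = 108,
                              n_slow_loci = 300L, n_fast_loci = 50L,
                              slow_rate_range = c(5e-4, 3e-3),
                              fast_rate_range = c(2e-2, 1e-1),
                              conflict_fraction = 0.5,
                              locus_length_range = c(300L, 2000L),
                              missing_taxon_fraction = 0.05,
                              model = gtr_model(c(1.2, 3.5, 0.9, 1.1, 4.0, 1.0),
                                                c(0.27, 0.23, 0.24, 0.26),
                                                gamma_shape = 2),
                              seed = 1L) {
  stopifnot(n_taxa >= 4, root_age > 0,
            n_slow_loci >= 0, n_fast_loci >= 0,
            all(slow_rate_range > 0), all(fast_rate_range > 0),
            conflict_fraction >= 0, conflict_fraction <= 1,
            all(locus_length_range >= 1),
            missing_taxon_fraction >= 0, missing_taxon_fraction < 1,
            inherits(model, "gtr_model"))
  structure(list(n_taxa = as.integer(n_taxa), root_age = root_age,
                 n_slow_loci = as.integer(n_slow_loci),
                 n_fast_loci = as.integer(n_fast_loci),
                 slow_rate_range = sort(slow_rate_range),
                 fast_rate_range = sort(fast_rate_range),
                 conflict_fraction = conflict_fraction,
                 locus_length_range = sort(as.integer(locus_length_range)),
                 missing_taxon_fraction = missing_taxon_fraction,
                 model = model, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a calibrated species chronogram
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, with node ages
#' rescaled so the root sits at `root_age`. Ultrametric by construction;
#' deterministic for a given seed.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param root_age Root age in Myr.
#' @param seed Seed.
#' @return A [as_chronogram()] chronogram with tips `t001`, `t002`, ...
#' @export
simulate_chronogram <- function(n_taxa, root_age = 108, seed = 1L) {
  stopifnot(n_taxa >= 2, root_age > 0)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  as_chronogram(tr)
}

# Perturb a chronogram by valid NNI-style subtree swaps: a child subtree of
# an internal node v is exchanged with one of v's siblings under v's parent
# u, keeping all node ages (and hence ultrametricity and the root age)
# intact. Swaps that would place a subtree above its new parent's age are
# rejected and resampled.
chronogram_nni <- function(chrono, n_moves = 2L, seed = 1L) {
  stopifnot(inherits(chrono, "chronogram"))
  with_seed(seed, {
    tr <- chrono
    n <- length(tr$tip.label)
    done <- 0L
    tries <- 0L
    while (done < n_moves && tries < 1000L) {
      tries <- tries + 1L
      ages <- node_ages(tr)
      edge <- tr$edge
      cand <- which(edge[, 2] > n) # internal edges u -> v
      e <- cand[sample.int(length(cand), 1)]
      u <- edge[e, 1]; v <- edge[e, 2]
      v_children <- which(edge[, 1] == v)
      u_children <- setdiff(which(edge[, 1] == u), e)
      if (!length(v_children) || !length(u_children)) next
      a_e <- v_children[sample.int(length(v_children), 1)] # subtree under v
      b_e <- u_children[sample.int(length(u_children), 1)] # sibling under u
      b_node <- edge[b_e, 2]
      if (ages[b_node] >= ages[v]) next # b would sit above its new parent v
      a_node <- edge[a_e, 2]
      tr$edge[a_e, 2] <- b_node
      tr$edge[b_e, 2] <- a_node
      tr$edge.length[a_e] <- ages[v] - ages[b_node]
      tr$edge.length[b_e] <- ages[u] - ages[a_node]
      done <- done + 1L
    }
    if (done < n_moves)
      warning("only ", done, " of ", n_moves, " NNI moves were feasible")
    attr(tr, "order") <- NULL # edge rows were permuted; force a true reorder
    as_chronogram(stats::reorder(tr, "cladewise"))
  })
}

#' Simulate one locus along a chronogram
#'
#' Draws a root sequence from the model's stationary frequencies and evolves
#' it edge-wise with GTR transition probabilities at branch length
#' `rate x duration x gamma-category rate`; each site's gamma category is
#' sampled once (matching the +Gamma inference assumption in expectation).
#'
#' @param chronogram A [as_chronogram()] tree (ages in Myr).
#' @param rate Clock rate in substitutions/site/Myr (>= 0).
#' @param model A [gtr_model()].
#' @param length Number of sites (>= 1).
#' @param seed Seed; the same seed reproduces the alignment exactly.
#' @param locus_id Locus identifier.
#' @return A [gene_alignment()] over the chronogram's tips.
#' @export
simulate_locus <- function(chronogram, rate, model = gtr_model(),
                           length = 1000L, seed = 1L, locus_id = "locus") {
  stopifnot(inherits(chronogram, "chronogram"), rate >= 0, length >= 1)
  with_seed(seed, {
    tr <- stats::reorder(chronogram, "cladewise") # preorder: parents first
    n <- base::length(tr$tip.label)
    nn <- n + tr$Nnode
    pi <- model$base_freqs
    eig <- rate_matrix_eigen(build_rate_matrix(model), pi)
    rates <- discretize_gamma(model$gamma_shape, model$n_categories)
    cat_of <- sample.int(base::length(rates), length, replace = TRUE)
    states <- matrix(NA_integer_, nn, length)
    root <- tr$edge[1, 1]
    states[root, ] <- sample.int(4, length, replace = TRUE, prob = pi)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      bl <- rate * tr$edge.length[e]
      child <- integer(length)
      for (c_i in seq_along(rates)) {
        idx <- which(cat_of == c_i)
        if (!base::length(idx)) next
        P <- pmat_from_eigen(eig, bl * rates[c_i])
        ps <- states[p, idx]
        for (s in 1:4) {
          w <- idx[ps == s]
          if (base::length(w))
            child[w] <- sample.int(4, base::length(w), replace = TRUE,
                                   prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(n), ]], n, length)
    rownames(m) <- tr$tip.label
    matrix_to_alignment(m, locus_id)
  })
}

#' Simulate a full multi-locus dataset with known truth
#'
#' Generates the species chronogram, then the configured numbers of slow
#' (clock-like, on the true tree) and fast loci; a configured fraction of
#' the fast loci evolve on a 2-NNI-perturbed topology, emulating loci with a
#' conflicting history. Per locus, taxa are dropped independently with the
#' configured probability (never below 4 retained taxa). All randomness
#' derives from the config seed via [mix_seed()], so equal configs give
#' byte-identical datasets.
#'
#' @param config A [simulation_config()].
#' @return A list of class `locus_dataset`: `loci` (list of
#'   [gene_alignment()]), `chronogram` (the true species chronogram),
#'   `truth` (tibble: `locus_id`, `true_rate`, `class`, `conflict`,
#'   `topology_id`, `n_taxa`, `length`), and `gene_trees` (named list of the
#'   generating chronograms for conflicting loci).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  chrono <- simulate_chronogram(config$n_taxa, config$root_age,
                                seed = mix_seed(config$seed, 1))
  n_loci <- config$n_slow_loci + config$n_fast_loci
  classes <- rep(c("slow", "fast"), c(config$n_slow_loci, config$n_fast_loci))
  rate_range <- function(cls)
    if (cls == "slow") config$slow_rate_range else config$fast_rate_range
  n_conflict <- round(config$conflict_fraction * config$n_fast_loci)
  conflict_idx <- if (config$n_fast_loci > 0 && n_conflict > 0)
    config$n_slow_loci +
      with_seed(mix_seed(config$seed, 2),
                sample.int(config$n_fast_loci, n_conflict))
  else integer(0)
  loci <- vector("list", n_loci)
  gene_trees <- list()
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    id <- sprintf("locus%03d", i)
    rr <- rate_range(classes[i])
    rate <- with_seed(mix_seed(config$seed, 10 + 4 * i),
                      exp(stats::runif(1, log(rr[1]), log(rr[2]))))
    len <- with_seed(mix_seed(config$seed, 11 + 4 * i),
                     sample(config$locus_length_range[1]:
                              config$locus_length_range[2], 1))
    conflict <- i %in% conflict_idx
    gtree <- if (conflict) {
      gt <- chronogram_nni(chrono, n_moves = 2L,
                           seed = mix_seed(config$seed, 12 + 4 * i))
      gene_trees[[id]] <- gt
      gt
    } else chrono
    aln <- simulate_locus(gtree, rate, config$model, len,
                          seed = mix_seed(config$seed, 13 + 4 * i),
                          locus_id = id)
    if (config$missing_taxon_fraction > 0) {
      dropped <- with_seed(mix_seed(config$seed, 14 + 4 * i),
                           stats::runif(config$n_taxa) <
                             config$missing_taxon_fraction)
      if (sum(!dropped) < 4) dropped[] <- FALSE
      if (any(dropped))
        aln <- gene_alignment(aln$seqs[!dropped], id)
    }
    loci[[i]] <- aln
    truth[[i]] <- tibble::tibble(
      locus_id = id, true_rate = rate, class = classes[i],
      conflict = conflict,
      topology_id = if (conflict) id else "species_tree",
      n_taxa = base::length(aln$taxa), length = len)
  }
  structure(list(loci = loci, chronogram = chrono,
                 truth = dplyr::bind_rows(truth), gene_trees = gene_trees,
                 config = config),
            class = "locus_dataset")
}

#' @export
print.locus_dataset <- function(x, ...) {
  cat("<locus_dataset> ", length(x$loci), " loci (",
      sum(x$truth$class == "slow"), " slow, ",
      sum(x$truth$class == "fast"), " fast, ",
      sum(x$truth$conflict), " conflicting) over ",
      x$config$n_taxa, " taxa\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Standard pipeline inputs: one FASTA per locus under `dir/loci/`, the true
#' chronogram and any conflicting gene trees as Newick, and the truth table
#' as TSV. Byte-identical across runs for equal configs.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "locus_dataset"))
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  for (a in dataset$loci)
    write_fasta(a, file.path(dir, "loci", paste0(a$locus_id, ".fasta")))
  writeLines(write_newick(dataset$chronogram),
             file.path(dir, "chronogram.nwk"))
  if (length(dataset$gene_trees)) {
    writeLines(vapply(dataset$gene_trees, write_newick, ""),
               file.path(dir, "conflict_gene_trees.nwk"))
  }
  tt <- as.data.frame(dataset$truth)
  tt$true_rate <- sprintf("%.10g", tt$true_rate)
  utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
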