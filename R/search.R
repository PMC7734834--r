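# Conversions between gtr_model and phangorn's pml parameterisation.
# phangorn orders the six exchangeabilities AC, AG, AT, CG, CT, GT, the same
# convention used here (cross-checked against log_likelihood in the tests).

aln_to_phyDat <- function(x) {
  m <- aln_matrix(x)
  phangorn::phyDat(m, type = "DNA")
}

fit_to_model <- function(fit) {
  gtr_model(exchangeabilities = fit$Q / fit$Q[6],
            base_freqs = fit$bf / sum(fit$bf),
            gamma_shape = if (fit$k > 1) fit$shape else 1,
            n_categories = fit$k)
}

nj_start_tree <- function(dat) {
  d <- phangorn::dist.ml(dat)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) { # taxon pairs with no overlapping determined sites
    mx <- max(dm[is.finite(dm)], 1)
    dm[!is.finite(dm)] <- 2 * mx
    d <- stats::as.dist(dm)
  }
  tr <- ape::unroot(ape::nj(d))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Maximum-likelihood tree search
#'
#' Infers an unrooted ML tree under GTR+Gamma: a neighbour-joining tree on ML
#' pairwise distances is used as the starting point, followed by a
#' hill climb over nearest-neighbour-interchange moves with branch-length
#' re-optimisation until no move improves the likelihood. The numerical
#' optimisation is delegated to \pkg{phangorn}'s `pml`/`optim.pml` engine;
#' the search is deterministic for a given input.
#'
#' @param aln A [gene_alignment()] or [concatenate()] supermatrix with at
#'   least 3 taxa (3 taxa return the unique unrooted topology with optimised
#'   branch lengths).
#' @param model Optional [gtr_model()] whose parameters are held fixed. If
#'   `NULL` (default), GTR exchangeabilities, base frequencies and the gamma
#'   shape are estimated by maximum likelihood during the search.
#' @param seed Seed recorded with the result (the search itself is
#'   deterministic; the seed feeds derived analyses such as bootstrapping).
#' @param start_tree Optional starting `phylo`; defaults to the NJ tree.
#' @param n_gamma Gamma categories when `model` is `NULL`.
#' @return An object of class `ml_fit`: `tree` (unrooted `phylo`),
#'   `log_lik`, `model` (the fitted or supplied [gtr_model()]) and `seed`.
#' @export
ml_tree_search <- function(aln, model = NULL, seed = 1L, start_tree = NULL,
                           n_gamma = 4L) {
  nt <- length(aln$taxa)
  if (nt < 3) stop("need at least 3 taxa for a tree")
  dat <- aln_to_phyDat(aln)
  tr0 <- if (!is.null(start_tree)) ape::unroot(start_tree) else nj_start_tree(dat)
  ctrl <- phangorn::pml.control(trace = 0)
  if (is.null(model)) {
    fit <- phangorn::pml(tr0, dat, k = n_gamma, shape = 1)
    fit <- phangorn::optim.pml(fit, model = "GTR", optGamma = n_gamma > 1,
                               optNni = nt > 3, optEdge = TRUE, control = ctrl)
  } else {
    fit <- phangorn::pml(tr0, dat, bf = unname(model$base_freqs),
                         Q = unname(model$exchangeabilities),
                         shape = model$gamma_shape, k = model$n_categories)
    fit <- phangorn::optim.pml(fit, optNni = nt > 3, optEdge = TRUE,
                               control = ctrl)
  }
  out_model <- if (is.null(model)) fit_to_model(fit) else model
  structure(list(tree = ape::unroot(fit$tree), log_lik = as.numeric(stats::logLik(fit)),
                 model = out_model, seed = as.integer(seed)),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit> ", length(x$tree$tip.label), " taxa, lnL = ",
      format(x$log_lik, digits = 10), "\n", sep = "")
  invisible(x)
}

# canonical split key for every internal non-root node of an unrooted tree;
# NA where the corresponding split is trivial
node_split_keys <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  anchor <- sort(tree$tip.label, method = "radix")[1]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  keys <- rep(NA_character_, tree$Nnode)
  for (i in seq_along(pp)) {
    node <- n + i
    if (node == root) next
    side <- labels[pp[[i]]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(labels, side)
    keys[i] <- paste(sort(side, method = "radix"), collapse = "\r")
  }
  keys
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement (each replicate has the
#' original length), re-runs the ML tree search on every replicate, and maps
#' the bipartition frequencies (x 100) onto the best tree inferred from the
#' original alignment. Model parameters are estimated once on the original
#' alignment and held fixed across replicates, and each replicate's NNI hill
#' climb starts from the best tree, in the spirit of the fast bootstrap of
#' large-scale ML programs; replicate seeds derive deterministically from the
#' master seed via [mix_seed()].
#'
#' @param aln A [gene_alignment()] or supermatrix (>= 4 taxa for non-trivial
#'   supports).
#' @param model Optional fixed [gtr_model()]; estimated from the data when
#'   `NULL`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Master seed.
#' @param full_search If `TRUE`, each replicate restarts from its own NJ tree
#'   instead of the best tree (slower, classic bootstrap).
#' @return An object of class `bootstrap_result`: `best_tree` (unrooted
#'   `phylo`, `node.label` holding supports in `[0, 100]`),
#'   `replicate_trees` (`multiPhylo`), `n_replicates`, `seed`, `model`,
#'   `log_lik` (of the original-alignment fit).
#' @export
bootstrap_support <- function(aln, model = NULL, n_replicates = 100L,
                              seed = 1L, full_search = FALSE) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) stop("need n_replicates >= 1")
  best <- ml_tree_search(aln, model = model, seed = seed)
  fixed <- best$model
  m <- aln_matrix(aln)
  L <- ncol(m)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- with_seed(mix_seed(seed, b),
                      sample.int(L, L, replace = TRUE))
    mb <- m[, cols, drop = FALSE]
    colnames(mb) <- NULL
    aln_b <- matrix_to_alignment(mb, paste0("bs", b))
    fit_b <- ml_tree_search(aln_b, model = fixed, seed = mix_seed(seed, b),
                            start_tree = if (full_search) NULL else best$tree)
    reps[[b]] <- fit_b$tree
  }
  class(reps) <- "multiPhylo"
  keys <- node_split_keys(best$tree)
  rep_keys <- unlist(lapply(reps, function(t) unique(nontrivial_splits(t))))
  counts <- table(rep_keys)
  supp <- ifelse(is.na(keys), NA_real_,
                 100 * as.vector(counts[keys]) / n_replicates)
  supp[!is.na(keys) & is.na(supp)] <- 0
  tree <- best$tree
  tree$node.label <- ifelse(is.na(supp), "", sprintf("%.10g", supp))
  structure(list(best_tree = tree, replicate_trees = reps,
                 n_replicates = n_replicates, seed = as.integer(seed),
                 model = fixed, log_lik = best$log_lik),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  s <- internal_supports(x$best_tree)
  cat("<bootstrap_result> ", x$n_replicates, " replicates; ",
      length(s), " internal edges; mean support ",
      sprintf("%.1f", mean(s)), "\n", sep = "")
  invisible(x)
}

# Node labels with the unrooting quirk resolved: when a rooted tree with a
# two-child root is unrooted, one child of the new basal node describes the
# same split as the old root and ape leaves the support on the root's label.
# If exactly one internal root-child lacks a label while the root carries
# one, move the root label onto that child.
effective_node_labels <- function(tr) {
  n <- length(tr$tip.label)
  lab <- tr$node.label
  if (is.null(lab)) return(NULL)
  root <- n + 1L
  root_lab <- lab[1]
  if (is.na(root_lab) || root_lab == "") return(lab)
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  kids <- kids[kids > n]
  empty <- kids[is.na(lab[kids - n]) | lab[kids - n] == ""]
  if (length(empty) == 1) lab[empty - n] <- root_lab
  lab
}

# numeric supports on the internal (non-root) edges of an unrooted tree
internal_supports <- function(tree) {
  if (length(tree$tip.label) < 4) return(numeric(0))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  if (tr$Nnode < 2) return(numeric(0))
  lab <- effective_node_labels(tr)
  if (is.null(lab)) stop("tree has no support annotations")
  keys <- node_split_keys(tr)
  idx <- which(!is.na(keys))
  supp <- suppressWarnings(as.numeric(lab[idx]))
  if (anyNA(supp)) stop("non-numeric support on an internal edge")
  supp
}

#' Average bootstrap support of a tree
#'
#' Arithmetic mean of the bootstrap supports over all internal (non-trivial)
#' bipartitions of the unrooted best tree — the gene-selection score.
#'
#' @param x A [bootstrap_support()] result, or a `phylo` whose internal
#'   node labels are numeric supports.
#' @return An object of class `support_summary` with fields
#'   `average_bootstrap` and `n_internal_edges`.
#' @export
average_bootstrap <- function(x) {
  tree <- if (inherits(x, "bootstrap_result")) x$best_tree else x
  stopifnot(inherits(tree, "phylo"))
  s <- internal_supports(tree)
  if (length(s) == 0)
    stop("tree has no internal edges (fewer than 4 taxa?)")
  structure(list(average_bootstrap = mean(s), n_internal_edges = length(s)),
            class = "support_summary")
}

#' @export
print.support_summary <- function(x, ...) {
  cat("<support_summary> mean support ",
      sprintf("%.2f", x$average_bootstrap), " over ",
      x$n_internal_edges, " internal edges\n", sep = "")
  invisible(x)
}

#' Write bootstrap replicate trees
#'
#' One Newick string per line — the standard input format for external
#' species-tree programs.
#'
#' @param result A [bootstrap_support()] result.
#' @param path Output path.
#' @export
write_replicate_trees <- function(result, path) {
  stopifnot(inherits(result, "bootstrap_result"))
  writeLines(vapply(result$replicate_trees, write_newick, ""), path)
  invisible(path)
}
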