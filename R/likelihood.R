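# IUPAC state vectors: rows are observed characters, columns A,C,G,T.
# Fully missing characters ('-', 'N', '?') carry no information (all ones);
# ambiguity codes restrict to their compatible subset.
state_vector_table <- local({
  tab <- rbind(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1))
  colnames(tab) <- c("A", "C", "G", "T")
  tab
})

# Pattern-compressed likelihood kernel for one character matrix.
# Holds per-taxon tip partial matrices (n_patterns x 4) and pattern weights;
# evaluation is then a function of (tree, edge lengths, model) only.
lik_kernel <- function(charmat) {
  if (nrow(charmat) == 0 || ncol(charmat) == 0) stop("empty alignment")
  bad <- setdiff(unique(as.vector(charmat)), rownames(state_vector_table))
  if (length(bad))
    stop("unsupported characters in alignment: ", paste(bad, collapse = ", "))
  cols <- apply(charmat, 2, paste0, collapse = "")
  first <- !duplicated(cols)
  pat_cols <- which(first)
  weights <- as.numeric(table(factor(cols, levels = cols[first])))
  tips <- lapply(seq_len(nrow(charmat)), function(r)
    state_vector_table[charmat[r, pat_cols], , drop = FALSE])
  names(tips) <- rownames(charmat)
  list(tips = tips, weights = weights, n_patterns = length(pat_cols),
       taxa = rownames(charmat))
}

row_max4 <- function(x) pmax(x[, 1], x[, 2], x[, 3], x[, 4])

# Core pruning evaluation. `tree` must be postorder-reordered with tips
# matched to kernel taxa; `edge_lengths` in expected substitutions/site.
kernel_loglik <- function(kern, tree_po, edge_lengths, model, eig = NULL) {
  pi <- model$base_freqs
  if (is.null(eig)) eig <- rate_matrix_eigen(build_rate_matrix(model), pi)
  rates <- discretize_gamma(model$gamma_shape, model$n_categories)
  k <- length(rates)
  n <- length(tree_po$tip.label)
  nn <- n + tree_po$Nnode
  root <- tree_po$edge[nrow(tree_po$edge), 1]
  tipmap <- match(tree_po$tip.label, kern$taxa)
  npat <- kern$n_patterns
  site_log <- matrix(0, npat, k)
  for (c_i in seq_len(k)) {
    partial <- vector("list", nn)
    logscale <- numeric(npat)
    for (e in seq_len(nrow(tree_po$edge))) {
      p <- tree_po$edge[e, 1]; ch <- tree_po$edge[e, 2]
      C <- if (ch <= n) kern$tips[[tipmap[ch]]] else partial[[ch]]
      P <- pmat_from_eigen(eig, edge_lengths[e] * rates[c_i])
      contrib <- C %*% t(P)
      if (is.null(partial[[p]])) partial[[p]] <- contrib
      else {
        x <- partial[[p]] * contrib
        m <- row_max4(x)
        m[m <= 0] <- 1
        logscale <- logscale + log(m)
        partial[[p]] <- x / m
      }
    }
    site_log[, c_i] <- log(as.vector(partial[[root]] %*% pi)) + logscale
  }
  mx <- apply(site_log, 1, max)
  site <- mx + log(rowMeans(exp(site_log - mx)))
  sum(kern$weights * site)
}

check_taxa_match <- function(tree, taxa) {
  extra <- setdiff(tree$tip.label, taxa)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(extra) || length(miss))
    stop("tree/alignment taxon mismatch; only in tree: {",
         paste(extra, collapse = ", "), "}; only in alignment: {",
         paste(miss, collapse = ", "), "}")
}

#' Phylogenetic log-likelihood under GTR+Gamma
#'
#' Felsenstein pruning over pattern-compressed sites with discrete-gamma rate
#' averaging (equal category weights). Gaps, `N` and `?` contribute all-ones
#' conditional vectors; IUPAC ambiguity codes contribute their compatible
#' subset. For a supermatrix, partitions may have their own models (a named
#' list matching the partition `locus_id`s) and the per-partition
#' log-likelihoods are summed on the shared tree.
#'
#' @param tree A `phylo` with branch lengths in expected substitutions/site;
#'   its leaf set must equal the alignment's taxa exactly.
#' @param x A [gene_alignment()] or [concatenate()] supermatrix.
#' @param model A [gtr_model()], or for a supermatrix optionally a named list
#'   of models keyed by `locus_id`.
#' @return Natural-log likelihood (a single number).
#' @export
log_likelihood <- function(tree, x, model) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  check_taxa_match(tree, x$taxa)
  tree_po <- stats::reorder(tree, "postorder")
  if (inherits(x, "supermatrix") && inherits(model, "list")) {
    ids <- x$partitions$locus_id
    if (!setequal(names(model), ids))
      stop("per-partition model list must be named by the partition locus_ids")
    m <- aln_matrix(x)
    tot <- 0
    for (i in seq_along(ids)) {
      sl <- m[, x$partitions$start[i]:x$partitions$end[i], drop = FALSE]
      tot <- tot + kernel_loglik(lik_kernel(sl), tree_po,
                                 tree_po$edge.length, model[[ids[i]]])
    }
    return(tot)
  }
  stopifnot(inherits(model, "gtr_model"))
  kernel_loglik(lik_kernel(aln_matrix(x)), tree_po, tree_po$edge.length, model)
}

#' Optimise branch lengths on a fixed topology
#'
#' Cycles over edges, optimising each branch length by bounded 1-D search
#' with all others held fixed, until the log-likelihood improves by less than
#' `tol` over a full sweep. Lengths are constrained to `bounds`; degenerate
#' data simply drives lengths to a bound.
#'
#' @param tree A `phylo`; its branch lengths are the starting point (missing
#'   lengths start at 0.1).
#' @param aln A [gene_alignment()] or supermatrix.
#' @param model A [gtr_model()].
#' @param tol Convergence tolerance on the log-likelihood per sweep.
#' @param bounds Length-2 numeric bounds on each branch length.
#' @param max_sweeps Safety cap on the number of sweeps.
#' @return The tree with optimised `edge.length` and attributes `logLik` and
#'   `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    bounds = c(1e-8, 50), max_sweeps = 50L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"))
  check_taxa_match(tree, aln$taxa)
  tree_po <- stats::reorder(tree, "postorder")
  if (is.null(tree_po$edge.length))
    tree_po$edge.length <- rep(0.1, nrow(tree_po$edge))
  tree_po$edge.length <- pmin(pmax(tree_po$edge.length, bounds[1]), bounds[2])
  kern <- lik_kernel(aln_matrix(aln))
  eig <- rate_matrix_eigen(build_rate_matrix(model), model$base_freqs)
  len <- tree_po$edge.length
  cur <- kernel_loglik(kern, tree_po, len, model, eig)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    prev <- cur
    for (e in seq_along(len)) {
      f <- function(l) {
        len2 <- len; len2[e] <- l
        -kernel_loglik(kern, tree_po, len2, model, eig)
      }
      opt <- stats::optimize(f, interval = bounds, tol = 1e-9)
      if (-opt$objective > cur) {
        len[e] <- opt$minimum
        cur <- -opt$objective
      }
    }
    if (cur - prev < tol || sweeps >= max_sweeps) break
  }
  tree_po$edge.length <- len
  attr(tree_po, "logLik") <- cur
  attr(tree_po, "sweeps") <- sweeps
  tree_po
}
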