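#' Read a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object. Numeric internal-node labels are the conventional carrier for
#' bootstrap support values and are preserved in `node.label`.
#'
#' @param text A Newick string, or the path to a file holding one.
#' @return A `phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr)) stop("failed to parse Newick string")
  tr
}

#' Write a Newick string
#'
#' Branch lengths are written to 10 significant digits so that
#' `read_newick(write_newick(t))` reproduces `t` up to that precision.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10)
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree.
# Each split is represented by the side NOT containing the lexicographically
# smallest tip label, sorted, joined with '\r' (a character that cannot occur
# in taxon labels used here).
nontrivial_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  if (n < 4) return(character(0))
  anchor <- sort(tr$tip.label, method = "radix")[1]
  pp <- ape::prop.part(tr)
  labels <- attr(pp, "labels")
  out <- character(0)
  for (i in seq_along(pp)) {       # i == 1 is the root node: all tips
    side <- labels[pp[[i]]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(labels, side)
    out <- c(out, paste(sort(side, method = "radix"), collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of the non-trivial bipartitions of two trees
#' over the same leaf set (topology only; branch lengths ignored).
#'
#' @param t1,t2 `phylo` objects with identical tip labels.
#' @return A non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  d <- union(setdiff(t1$tip.label, t2$tip.label),
             setdiff(t2$tip.label, t1$tip.label))
  if (length(d))
    stop("trees have different leaf sets; differing: ", paste(d, collapse = ", "))
  s1 <- nontrivial_splits(t1)
  s2 <- nontrivial_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Collapse poorly supported branches
#'
#' Contracts every internal edge whose bootstrap support is strictly below
#' `threshold` into a polytomy (leaf edges are never touched). This is the
#' usual preparation of per-locus gene trees before coalescent species-tree
#' estimation, where weakly supported resolution is treated as absent.
#' Collapsed edges lose their branch length; remaining edge lengths are kept.
#'
#' @param tree A `phylo` object whose internal nodes carry numeric support
#'   labels. An internal edge without a numeric annotation is an error.
#' @param threshold Support threshold; edges with support `< threshold` are
#'   collapsed (so support exactly at the threshold is retained).
#' @return An unrooted `phylo` object, possibly multifurcating.
#' @export
contract_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), is.numeric(threshold), length(threshold) == 1)
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  root <- n + 1L
  if (tr$Nnode < 2) return(tr) # star or near-star: no internal edges
  lab <- effective_node_labels(tr)
  if (is.null(lab)) stop("tree has no support annotations")
  inner <- setdiff((n + 1L):(n + tr$Nnode), root)
  supp <- suppressWarnings(as.numeric(lab[inner - n]))
  if (anyNA(supp))
    stop("internal edge(s) without numeric support annotation; cannot contract")
  bad <- inner[supp < threshold]
  if (!length(bad)) return(tr)
  edge <- tr$edge
  elen <- tr$edge.length
  parent_of <- integer(n + tr$Nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  resolve <- function(u) { while (u %in% bad) u <- parent_of[u]; u }
  keep <- !(edge[, 2] %in% bad)
  e2 <- cbind(vapply(edge[keep, 1], resolve, 1L), edge[keep, 2])
  l2 <- if (!is.null(elen)) elen[keep] else NULL
  children <- split(seq_len(nrow(e2)), e2[, 1])
  node_lab <- function(v) {
    if (v == root) return("")
    s <- lab[v - n]
    if (is.na(s)) "" else s
  }
  rec <- function(v, ei) {
    kids <- children[[as.character(v)]]
    body <- if (v <= n) tr$tip.label[v]
    else paste0("(", paste(vapply(kids, function(k) rec(e2[k, 2], k), ""),
                           collapse = ","), ")", node_lab(v))
    if (!is.null(ei) && !is.null(l2)) paste0(body, ":", sprintf("%.10g", l2[ei]))
    else body
  }
  ape::read.tree(text = paste0(rec(root, NULL), ";"))
}

#' Prune a tree to a taxon subset
#'
#' Returns the subtree induced by `taxa`: unary nodes are suppressed and path
#' lengths among the retained taxa are preserved. For a [as_chronogram()]
#' chronogram the result is again ultrametric, with the new root at the most
#' recent common ancestor of the retained taxa (ages keep their original
#' scale).
#'
#' @param tree A `phylo` or chronogram.
#' @param taxa Character vector of tip labels to keep (at least 2, all
#'   present in the tree).
#' @return Pruned tree of the same kind.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa to keep")
  was_chrono <- inherits(tree, "chronogram")
  out <- ape::keep.tip(tree, taxa)
  out$root.edge <- NULL # new root is the MRCA of the retained taxa
  if (was_chrono) as_chronogram(out) else out
}

#' Mark a rooted ultrametric tree as a chronogram
#'
#' Validates ultrametricity (all root-to-tip path lengths equal within a
#' relative tolerance) and attaches the `chronogram` class. Branch lengths
#' are interpreted as time (Myr); the root age is the common root-to-tip
#' depth.
#'
#' @param tree A rooted `phylo` with branch lengths in time units.
#' @param tol Relative tolerance on root-to-tip depth variation.
#' @return The tree with class `c("chronogram", "phylo")`.
#' @export
as_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("chronogram must be rooted")
  if (is.null(tree$edge.length)) stop("chronogram needs branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_along(tree$tip.label)]
  if (max(tipd) <= 0) stop("tree has zero height")
  if ((max(tipd) - min(tipd)) / max(tipd) > tol)
    stop("tree is not ultrametric (root-to-tip depths differ by more than tol)")
  class(tree) <- unique(c("chronogram", class(tree)))
  tree
}

#' Root age of a chronogram
#' @param chronogram A [as_chronogram()] tree.
#' @return Root age in the tree's time units.
#' @export
root_age <- function(chronogram) {
  stopifnot(inherits(chronogram, "chronogram"))
  max(ape::node.depth.edgelength(chronogram)[seq_along(chronogram$tip.label)])
}

#' Node ages of a chronogram
#'
#' @param chronogram A [as_chronogram()] tree.
#' @return Numeric vector of ages (time before present) for all nodes in ape
#'   numbering (tips first); tip ages are exactly 0.
#' @export
node_ages <- function(chronogram) {
  stopifnot(inherits(chronogram, "chronogram"))
  depth <- ape::node.depth.edgelength(chronogram)
  ra <- max(depth[seq_along(chronogram$tip.label)])
  ages <- ra - depth
  ages[seq_along(chronogram$tip.label)] <- 0
  pmax(ages, 0)
}

#' Project a phylogram onto a calibrated chronogram
#'
#' Converts a rooted tree with branch lengths in substitutions/site into an
#' ultrametric time tree by mean-path smoothing: each internal node's
#' tentative age is the mean root-to-tip path length below it, ages are
#' forced to be monotone along root-to-tip paths, and the whole tree is
#' rescaled so the root sits at `root_age`. This is a deliberately simple
#' clock projection: it preserves the relative depth structure needed for
#' rate ranking, not a model-based dating.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param root_age Calibration age for the root (e.g. 108 Ma).
#' @return A [as_chronogram()] chronogram with branch lengths in the units of
#'   `root_age`.
#' @export
calibrate_chronogram <- function(tree, root_age) {
  stopifnot(inherits(tree, "phylo"), is.numeric(root_age), root_age > 0)
  if (!ape::is.rooted(tree)) stop("tree must be rooted before calibration")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  sumd <- numeric(nn) # sum of distances to descendant tips
  cnt <- integer(nn)
  cnt[seq_len(n)] <- 1L
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]; l <- tr$edge.length[k]
    sumd[p] <- sumd[p] + sumd[ch] + l * cnt[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  age <- numeric(nn)
  age[(n + 1L):nn] <- sumd[(n + 1L):nn] / cnt[(n + 1L):nn]
  # enforce child age < parent age (postorder guarantees children first)
  eps <- 1e-9 * max(age)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    if (ch > n && age[p] <= age[ch]) age[p] <- age[ch] + eps
  }
  root <- n + 1L
  age <- age * root_age / age[root]
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  as_chronogram(out)
}
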