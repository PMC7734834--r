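# Shared fixtures and independent oracles. Everything here deliberately
# avoids the package's own computational paths: transition matrices come from
# Matrix::expm, gamma band means from numerical quadrature, likelihoods from
# exhaustive internal-state enumeration, splits from graph bisection.

rand_model <- function(seed, k = 4L) {
  set.seed(seed)
  f <- rgamma(4, 5, 1); f <- f / sum(f)
  gtr_model(exchangeabilities = rgamma(6, 2, 1), base_freqs = f,
            gamma_shape = runif(1, 0.3, 3), n_categories = k)
}

rand_alignment <- function(n_taxa, length, seed, gap_prob = 0,
                           locus_id = "locus") {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), n_taxa * length, replace = TRUE)
  if (gap_prob > 0) {
    miss <- runif(n_taxa * length) < gap_prob
    chars[miss] <- sample(c("-", "N", "?"), sum(miss), replace = TRUE)
  }
  m <- matrix(chars, n_taxa, length)
  rownames(m) <- sprintf("s%02d", seq_len(n_taxa))
  gene_alignment(m, locus_id)
}

# gamma band means by quadrature (independent of discretize_gamma)
gamma_band_means <- function(alpha, k) {
  q <- c(0, stats::qgamma(seq_len(k - 1) / k, alpha, alpha), Inf)
  vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     q[i], q[i + 1], rel.tol = 1e-10)$value * k
  }, 0)
}

# allowed base states (indices into A,C,G,T) for one observed character
allowed_states <- function(ch) {
  map <- list(A = 1, C = 2, G = 3, T = 4, R = c(1, 3), Y = c(2, 4),
              S = c(2, 3), W = c(1, 4), K = c(3, 4), M = c(1, 2),
              B = 2:4, D = c(1, 3, 4), H = c(1, 2, 4), V = 1:3,
              N = 1:4, `-` = 1:4, `?` = 1:4)
  map[[ch]]
}

# Exhaustive-likelihood oracle: sums over every assignment of states to the
# internal nodes, with transition matrices from Matrix::expm.
brute_force_loglik <- function(tree, aln, model) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  pi <- unname(model$base_freqs)
  Q <- build_rate_matrix(model)
  rates <- gamma_band_means(model$gamma_shape, model$n_categories)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  stopifnot(length(root) == 1)
  internal <- sort(unique(tree$edge[, 1]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  lik_mat <- matrix(0, ncol(m), length(rates))
  for (r_i in seq_along(rates)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      as.matrix(Matrix::expm(Q * tree$edge.length[e] * rates[r_i])))
    for (site in seq_len(ncol(m))) {
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[internal] <- grid[g, ]
        p <- pi[st[root]]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          if (ch <= n) {
            ok <- allowed_states(m[tree$tip.label[ch], site])
            p <- p * sum(P[[e]][st[par], ok])
          } else p <- p * P[[e]][st[par], st[ch]]
        }
        lik <- lik + p
      }
      lik_mat[site, r_i] <- lik
    }
  }
  sum(log(rowMeans(lik_mat)))
}

# naive bipartitions: delete each internal edge, flood-fill the two halves
naive_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  edges <- tr$edge
  anchor <- sort(tr$tip.label)[1]
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 2] <= n) next
    adj <- edges[-e, , drop = FALSE]
    reach <- edges[e, 2]
    repeat {
      hit <- adj[, 1] %in% reach | adj[, 2] %in% reach
      new <- setdiff(unique(as.vector(adj[hit, ])), reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    side <- tr$tip.label[reach[reach <= n]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(tr$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

# forward Yule sampler (independent of ape::rphylo): normalized non-root
# internal node ages of a pure-birth tree with n tips
fwd_yule_ages <- function(n) {
  t <- 0
  times <- numeric(n - 1)
  for (k in 2:(n - 1)) { t <- t + stats::rexp(1, k); times[k] <- t }
  present <- t + stats::rexp(1, n)
  ages <- present - times
  (ages / ages[1])[-1]
}

# tiny deterministic alignment builder for hand-written examples
aln_from <- function(..., locus_id = "toy") {
  s <- c(...)
  gene_alignment(s, locus_id)
}
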