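#' GTR+Gamma substitution model
#'
#' Constructs a general time-reversible (GTR) nucleotide substitution model
#' with discrete-gamma among-site rate variation. The model is parameterised
#' by six symmetric exchangeabilities (order AC, AG, AT, CG, CT, GT),
#' stationary base frequencies \eqn{\pi_A..\pi_T}, a gamma shape
#' \eqn{\alpha}, and the number of equal-probability gamma categories.
#'
#' @param exchangeabilities Numeric vector of 6 non-negative relative rates
#'   in the order AC, AG, AT, CG, CT, GT. At least one must be positive.
#' @param base_freqs Numeric vector of 4 positive frequencies (A, C, G, T)
#'   summing to 1.
#' @param gamma_shape Positive gamma shape parameter \eqn{\alpha}. Small
#'   values mean strong rate heterogeneity among sites.
#' @param n_categories Number of discrete gamma categories (default 4, the
#'   de facto standard).
#' @return An object of class `gtr_model`.
#' @examples
#' m <- gtr_model()                        # Jukes-Cantor-like defaults
#' m <- gtr_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3), gamma_shape = 0.5)
#' @export
gtr_model <- function(exchangeabilities = rep(1, 6),
                      base_freqs = rep(0.25, 4),
                      gamma_shape = 1,
                      n_categories = 4L) {
  exchangeabilities <- as.numeric(exchangeabilities)
  base_freqs <- as.numeric(base_freqs)
  if (length(exchangeabilities) != 6 || any(exchangeabilities < 0) ||
      all(exchangeabilities == 0))
    stop("'exchangeabilities' must be 6 non-negative values, not all zero")
  if (length(base_freqs) != 4 || any(base_freqs <= 0))
    stop("'base_freqs' must be 4 positive values")
  if (abs(sum(base_freqs) - 1) > 1e-12)
    stop("'base_freqs' must sum to 1 (got ", format(sum(base_freqs), digits = 15), ")")
  if (!is.numeric(gamma_shape) || length(gamma_shape) != 1 || gamma_shape <= 0)
    stop("'gamma_shape' must be a single positive number")
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 1)
    stop("'n_categories' must be an integer >= 1")
  structure(
    list(exchangeabilities = stats::setNames(exchangeabilities,
                                             c("AC", "AG", "AT", "CG", "CT", "GT")),
         base_freqs = stats::setNames(base_freqs, c("A", "C", "G", "T")),
         gamma_shape = gamma_shape,
         n_categories = n_categories),
    class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model\n")
  cat("  exchangeabilities:",
      paste(names(x$exchangeabilities), signif(x$exchangeabilities, 4),
            sep = "=", collapse = " "), "\n")
  cat("  base frequencies: ",
      paste(names(x$base_freqs), signif(x$base_freqs, 4),
            sep = "=", collapse = " "), "\n")
  cat("  gamma shape:", signif(x$gamma_shape, 4),
      " categories:", x$n_categories, "\n")
  invisible(x)
}

#' Normalised GTR instantaneous rate matrix
#'
#' Builds the 4x4 instantaneous rate matrix Q with off-diagonals
#' \eqn{q_{ij} = s_{ij} \pi_j}, rows summing to zero, scaled so that the
#' expected number of substitutions per unit branch length equals 1
#' (\eqn{-\sum_i \pi_i q_{ii} = 1}). Branch lengths used with this matrix are
#' therefore in expected substitutions per site.
#'
#' @param model A [gtr_model()].
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "gtr_model"))
  pi <- model$base_freqs
  s <- model$exchangeabilities
  if (any(pi <= 0)) stop("degenerate base frequencies")
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("rate matrix has zero total rate")
  Q / mu
}

# Eigendecomposition of a reversible Q via the symmetric similarity transform
# B = D^{1/2} Q D^{-1/2} with D = diag(pi). Returns the pieces needed to form
# P(t) = U exp(lambda t) Uinv cheaply for many t.
rate_matrix_eigen <- function(Q, base_freqs) {
  sp <- sqrt(base_freqs)
  B <- (sp %o% (1 / sp)) * Q
  B <- (B + t(B)) / 2 # symmetrise against round-off
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / sp      # D^{-1/2} V  (rows scaled)
  Uinv <- t(e$vectors * sp) # V' D^{1/2}
  list(values = e$values, U = U, Uinv = Uinv)
}

pmat_from_eigen <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix P(t)
#'
#' Computes \eqn{P(t) = e^{Qt}} for a reversible rate matrix by symmetric
#' eigendecomposition. Rows sum to 1; entries are clipped to `[0, 1]` against
#' round-off.
#'
#' @param rate_matrix A 4x4 rate matrix from [build_rate_matrix()].
#' @param t Non-negative branch length (expected substitutions per site).
#' @param base_freqs Stationary frequencies of `rate_matrix`. If `NULL` they
#'   are recovered from the null space of `t(rate_matrix)`.
#' @return A 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(rate_matrix, t, base_freqs = NULL) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number")
  if (is.null(base_freqs)) base_freqs <- stationary_freqs(rate_matrix)
  eig <- rate_matrix_eigen(rate_matrix, base_freqs)
  pmat_from_eigen(eig, t)
}

stationary_freqs <- function(Q) {
  # left null vector of Q
  ns <- svd(t(Q))
  v <- ns$u[, 4]
  v <- abs(v)
  v / sum(v)
}

#' Discrete-gamma relative rates
#'
#' Divides a gamma(\eqn{\alpha}, rate \eqn{\alpha}) distribution (mean 1)
#' into `k` equal-probability bands and returns the mean rate of each band,
#' renormalised so the category mean is exactly 1. This is the standard
#' discrete approximation to gamma-distributed among-site rate variation.
#'
#' @param alpha Positive gamma shape.
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` non-decreasing rates with mean 1.
#' @examples
#' discretize_gamma(1, 4)
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("'alpha' must be a single positive number")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("'k' must be an integer >= 1")
  if (k == 1) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # E[X | band] * P(band)^{-1}: incomplete-mean identity via shape alpha + 1
  cum <- stats::pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  rates <- k * diff(cum)
  rates / mean(rates)
}
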