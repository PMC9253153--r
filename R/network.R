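#' Validate a correlation matrix for network estimation
#'
#' Checks symmetry (within 1e-10), an exactly-unit diagonal, entries between
#' -1 and 1, and positive semi-definiteness (smallest eigenvalue >= -1e-8).
#'
#' @param S Square numeric matrix.
#' @return `S`, invisibly, with the diagonal forced to exactly 1.
#' @export
validate_cor_matrix <- function(S) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S))
    stop("S must be a square numeric matrix")
  if (max(abs(S - t(S))) > 1e-10)
    stop("S is not symmetric (max asymmetry ",
         format(max(abs(S - t(S)))), ")")
  if (max(abs(diag(S) - 1)) > 1e-10)
    stop("S must have a unit diagonal")
  if (any(abs(S) > 1 + 1e-10))
    stop("correlation entries must lie in [-1, 1]")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("S is not positive semi-definite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")")
  diag(S) <- 1
  invisible(S)
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Omega) - trace(S Omega) - lambda * sum_{i != j}
#' |Omega_ij|` over positive-definite precision matrices by block coordinate
#' descent. The diagonal is unpenalized by default. Convergence is declared
#' when the working covariance changes by less than `tol` elementwise
#' between sweeps.
#'
#' @param S Correlation (or covariance) matrix.
#' @param lambda Nonnegative L1 penalty.
#' @param penalize_diagonal Penalize the diagonal as well (default `FALSE`).
#' @param tol Convergence tolerance (default 1e-10).
#' @param maxit Maximum outer sweeps.
#' @return List with elements `omega` (precision matrix), `w` (estimated
#'   covariance), and `converged`.
#' @export
#' @examples
#' S <- neck_pain_cor()
#' fit <- glasso_fit(S, lambda = 0.05)
#' max(abs(solve(glasso_fit(S, 0)$omega) - S)) # lambda = 0 inverts S
glasso_fit <- function(S, lambda, penalize_diagonal = FALSE,
                       tol = 1e-10, maxit = 10000) {
  S <- unclass(validate_psd(S))
  if (lambda < 0) stop("lambda must be nonnegative")
  fit <- glasso_fit_cpp(S, lambda, penalize_diagonal, tol, maxit)
  if (!fit$converged)
    stop("glasso did not converge after ", maxit, " sweeps at lambda = ",
         format(lambda))
  dimnames(fit$omega) <- dimnames(S)
  fit
}

# Lighter validation used internally: symmetric and PD enough to fit.
validate_psd <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  S
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 L + E log(n) + 4 gamma E log(p)` with Gaussian log-likelihood
#' `L = (n / 2) (log det Omega - trace(S Omega))` and `E` the number of
#' nonzero off-diagonal entries in the upper triangle. `gamma = 0` recovers
#' the ordinary BIC penalty.
#'
#' @param omega Positive-definite precision matrix.
#' @param S Sample correlation/covariance matrix.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (>= 0).
#' @param zero_tol Threshold below which an entry counts as zero.
#' @return Scalar criterion value.
#' @export
ebic_score <- function(omega, S, n, gamma = 0.5, zero_tol = 1e-8) {
  p <- nrow(omega)
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("omega must be positive definite")
  L <- (n / 2) * (as.numeric(ld$modulus) - sum(S * omega))
  E <- sum(abs(omega[upper.tri(omega)]) > zero_tol)
  -2 * L + E * log(n) + 4 * gamma * E * log(p)
}

#' Partial correlations from a precision matrix
#'
#' Edge weights of the Gaussian graphical model:
#' `w_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, with a zero diagonal.
#'
#' @param omega Precision matrix with strictly positive diagonal.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
partial_correlations <- function(omega) {
  if (any(diag(omega) <= 0))
    stop("precision matrix must have a positive diagonal")
  d <- 1 / sqrt(diag(omega))
  w <- -omega * outer(d, d)
  diag(w) <- 0
  (w + t(w)) / 2
}

#' Penalty-path configuration for EBIC-glasso
#'
#' @param n_lambdas Number of penalties on the log-spaced path (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   absolute off-diagonal correlation (default 0.01).
#' @param penalize_diagonal Penalize the precision diagonal (default `FALSE`).
#' @return A `necknet_path_config` list.
#' @export
path_config <- function(n_lambdas = 100, lambda_min_ratio = 0.01,
                        penalize_diagonal = FALSE) {
  stopifnot(n_lambdas >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 penalize_diagonal = isTRUE(penalize_diagonal)),
            class = "necknet_path_config")
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a log-spaced penalty path from
#' `lambda_max` (the largest absolute off-diagonal correlation, where the
#' network is empty) down to `lambda_max * lambda_min_ratio`, scores every
#' model with the EBIC, and returns the minimizer. Ties are broken towards
#' the larger penalty (the sparser model).
#'
#' @param S Correlation matrix (validated with [validate_cor_matrix()]).
#' @param n Sample size behind `S`; must exceed the number of nodes.
#' @param gamma EBIC hyperparameter (default 0.5; use 0 for the exploratory
#'   BIC-type selection).
#' @param path A [path_config()].
#' @param zero_tol Edge-zero threshold on absolute weights.
#' @return A `necknet_network` list: `weights` (partial-correlation matrix),
#'   `precision`, `lambda`, `gamma`, `ebic`, `edge_count`, `n`,
#'   `node_labels`, and the full `path` data frame (lambda, edge count,
#'   EBIC per model).
#' @export
#' @examples
#' net <- select_network(neck_pain_cor(), n = 100, gamma = 0)
#' net$edge_count
select_network <- function(S, n, gamma = 0.5, path = path_config(),
                           zero_tol = 1e-8) {
  S <- validate_cor_matrix(S)
  p <- nrow(S)
  if (n <= p) stop("sample size n must exceed the number of nodes")
  labels <- rownames(S)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))

  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max == 0) lambda_max <- 1e-4  # diagonal input: empty network
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * path$lambda_min_ratio),
                     length.out = path$n_lambdas))
  fits <- glasso_path_cpp(unclass(S), lambdas, path$penalize_diagonal,
                          1e-8, 1000, zero_tol)
  if (!any(fits$converged)) stop("no penalty on the path converged")

  # EBIC = -2 L + E log n + 4 gamma E log p, L = (n/2)(log det - trace)
  L <- (n / 2) * (fits$logdet - fits$trace_so)
  edges <- fits$edges
  scores <- -2 * L + edges * log(n) + 4 * gamma * edges * log(p)
  scores[!fits$converged | !is.finite(fits$logdet)] <- NA
  best <- which.min(scores)  # lambdas descend, so first minimum is sparsest
  omega <- fits$omega[, , best]
  dimnames(omega) <- list(labels, labels)
  weights <- partial_correlations(omega)
  weights[abs(weights) <= zero_tol] <- 0

  structure(list(
    weights = weights,
    precision = omega,
    lambda = lambdas[best],
    gamma = gamma,
    ebic = scores[best],
    edge_count = sum(abs(weights[upper.tri(weights)]) > zero_tol),
    n = n,
    node_labels = labels,
    path = data.frame(lambda = lambdas, edge_count = edges, ebic = scores)),
    class = "necknet_network")
}

#' @export
print.necknet_network <- function(x, ...) {
  p <- length(x$node_labels)
  cat("Regularized partial-correlation network (", p, " nodes)\n", sep = "")
  cat("  edges: ", x$edge_count, " of ", p * (p - 1) / 2,
      "   lambda = ", signif(x$lambda, 4),
      "   gamma = ", x$gamma,
      "   EBIC = ", round(x$ebic, 2), "\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' Quantile-stratified correlations: Simpson's-paradox decomposition
#'
#' Splits participants into quantile groups of a conditioning feature and
#' contrasts the marginal Pearson correlation of two features with their
#' within-group correlations. A sign reversal between the marginal and the
#' within-group correlations is the hallmark of a common-effect (collider
#' or confounder) structure, as seen for ROM-SPARC conditioned on movement
#' velocity.
#'
#' @param table Data frame of participant features.
#' @param x,y Names of the two features to correlate.
#' @param conditioner Name of the stratifying feature.
#' @param n_groups Number of quantile groups (default 3: low/moderate/high).
#' @param min_cases Minimum group size; smaller groups are skipped with a
#'   warning (default 5).
#' @return List with `marginal` (pooled Pearson r) and `groups`, a data
#'   frame of group label, size, and within-group r (NA when skipped).
#' @export
simpson_decomposition <- function(table, x, y, conditioner, n_groups = 3,
                                  min_cases = 5) {
  stopifnot(n_groups >= 2)
  for (v in c(x, y, conditioner))
    if (!v %in% names(table)) stop("unknown feature: ", v)
  z <- table[[conditioner]]
  br <- quantile(z, probs = seq(0, 1, length.out = n_groups + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  g <- cut(z, breaks = unique(br), include.lowest = TRUE,
           labels = FALSE)
  out <- data.frame(group = seq_len(max(g)), n = NA_integer_, r = NA_real_)
  for (k in seq_len(max(g))) {
    sel <- g == k
    out$n[k] <- sum(sel)
    if (sum(sel) < min_cases || sd(table[[x]][sel]) == 0 ||
        sd(table[[y]][sel]) == 0) {
      warning("group ", k, " degenerate or too small; skipped")
      next
    }
    out$r[k] <- cor(table[[x]][sel], table[[y]][sel])
  }
  list(marginal = cor(table[[x]], table[[y]]), groups = out)
}
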