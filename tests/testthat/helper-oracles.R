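# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so they can serve as ground truth.

# random correlation matrix from a random full-rank factor
rand_cor <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  stats::cov2cor(crossprod(A))
}

# random sparse symmetric weight matrix with zero diagonal
rand_weight_matrix <- function(p, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, p, p)
  ut <- which(upper.tri(w))
  on <- sample(ut, ceiling(density * length(ut)))
  w[on] <- runif(length(on), 0.1, 0.8) * sample(c(-1, 1), length(on), TRUE)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  dimnames(w) <- list(paste0("n", 1:p), paste0("n", 1:p))
  w
}

# shortest-path distances by Floyd-Warshall over 1/|w| edge lengths
floyd_distances <- function(weights) {
  p <- nrow(weights)
  d <- matrix(Inf, p, p)
  diag(d) <- 0
  for (i in 1:p) for (j in 1:p)
    if (i != j && abs(weights[i, j]) > 0) d[i, j] <- 1 / abs(weights[i, j])
  for (k in 1:p) for (i in 1:p) for (j in 1:p)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(weights)
  d
}

# betweenness by exhaustive enumeration of simple paths, fractional credit
# among ties
enum_betweenness <- function(weights, tol = 1e-9) {
  p <- nrow(weights)
  btw <- numeric(p)
  len <- function(path) {
    sum(vapply(seq_len(length(path) - 1), function(i)
      1 / abs(weights[path[i], path[i + 1]]), numeric(1)))
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- path; return() }
      for (u in which(abs(weights[v, ]) > 0))
        if (!u %in% path) walk(c(path, u))
    }
    walk(s)
    out
  }
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, len, numeric(1))
    short <- paths[lens < min(lens) + tol]
    for (pa in short) {
      interior <- setdiff(pa, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(short)
    }
  }
  names(btw) <- rownames(weights)
  btw
}

# hub-structured 6-node model: one high-strength hub plus a periphery, so
# the node-strength profile is strongly varied (as in the empirical network,
# where velocity is the hub)
hub_model <- function() {
  p <- 6
  pc <- matrix(0, p, p)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(5, 6), c(4, 5))
  vals <- c(0.45, 0.4, 0.35, 0.2, 0.3, 0.15)
  for (k in seq_len(nrow(edges))) {
    pc[edges[k, 1], edges[k, 2]] <- vals[k]
    pc[edges[k, 2], edges[k, 1]] <- vals[k]
  }
  omega <- diag(p) - pc
  stopifnot(min(eigen(omega, only.values = TRUE)$values) > 0)
  list(omega = omega, partial = pc, sigma = stats::cov2cor(solve(omega)))
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / sd(x)^3
}

# variance of a standard normal truncated to [a, b]
truncnorm_var <- function(a, b) {
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- (da - db) / Z
  1 + (ada - bdb) / Z - m^2
}

# within-group correlation of (x, y) given conditioner c in [a, b] for a
# trivariate Gaussian with correlation matrix R (order x, y, c)
cond_group_cor <- function(R, a, b) {
  bx <- R[1, 3]; by <- R[2, 3]
  rxy <- R[1, 2]
  res_xy <- rxy - bx * by
  res_xx <- 1 - bx^2
  res_yy <- 1 - by^2
  v <- truncnorm_var(a, b)
  (res_xy + bx * by * v) /
    sqrt((res_xx + bx^2 * v) * (res_yy + by^2 * v))
}

# penalized glasso objective: log det O - tr(SO) - lambda * sum offdiag |O|
glasso_objective <- function(omega, S, lambda) {
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(S * omega) -
    lambda * sum(abs(omega[upper.tri(omega)])) * 2
}

# sparse 6-node precision matrix with known support (8 edges) used as the
# generating truth in recovery tests
known_sparse_model <- function() {
  p <- 6
  pc <- matrix(0, p, p)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4),
                 c(4, 5), c(5, 6), c(2, 6), c(3, 6))
  vals <- c(0.35, -0.25, 0.2, 0.3, -0.35, 0.25, 0.15, -0.2)
  for (k in seq_len(nrow(edges))) {
    pc[edges[k, 1], edges[k, 2]] <- vals[k]
    pc[edges[k, 2], edges[k, 1]] <- vals[k]
  }
  omega <- diag(p) - pc   # unit partial variances: Omega_ij = -pc_ij
  stopifnot(min(eigen(omega, only.values = TRUE)$values) > 0)
  sigma <- stats::cov2cor(solve(omega))
  list(omega = omega, partial = pc, sigma = sigma,
       support = abs(pc[upper.tri(pc)]) > 0)
}
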