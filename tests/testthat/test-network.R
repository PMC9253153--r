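test_that("unpenalized glasso equals direct matrix inversion", {
  for (s in 1:5) {
    S <- rand_cor(6, seed = s)
    fit <- glasso_fit(S, lambda = 0)
    expect_lt(max(abs(fit$omega - solve(S))), 1e-5)
  }
})

test_that("full shrinkage empties the network", {
  S <- neck_pain_cor()
  fit <- glasso_fit(S, lambda = max(abs(S[upper.tri(S)])))
  off <- fit$omega; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-10)
})

test_that("glasso satisfies the penalized-likelihood optimality conditions", {
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  lambda <- 0.1
  fit <- glasso_fit(S, lambda)
  W <- solve(fit$omega)

  # KKT: W_ii = S_ii; for omega_ij != 0, W_ij = S_ij + lambda sign(omega_ij);
  # for omega_ij = 0, |W_ij - S_ij| <= lambda
  expect_lt(max(abs(diag(W) - diag(S))), 1e-6)
  for (i in 1:2) for (j in (i + 1):3) {
    if (abs(fit$omega[i, j]) > 1e-8) {
      expect_lt(abs(W[i, j] - S[i, j] - lambda * sign(fit$omega[i, j])),
                1e-5)
    } else {
      expect_lte(abs(W[i, j] - S[i, j]), lambda + 1e-8)
    }
  }

  # a derivative-free optimizer over the 6 free entries cannot beat it
  obj <- function(par) {
    om <- matrix(0, 3, 3)
    diag(om) <- par[1:3]
    om[upper.tri(om)] <- par[4:6]
    om[lower.tri(om)] <- t(om)[lower.tri(om)]
    -glasso_objective(om, S, lambda)
  }
  start <- c(diag(fit$omega), fit$omega[upper.tri(fit$omega)])
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  expect_lt(-opt$value - glasso_objective(fit$omega, S, lambda), 1e-4)
})

test_that("EBIC reduces to BIC at gamma 0 and penalizes density", {
  om <- matrix(c(2, -0.5, -0.5, 1.5), 2)
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  n <- 50
  L <- (n / 2) * (log(det(om)) - sum(S * om))
  expect_equal(ebic_score(om, S, n, gamma = 0), -2 * L + 1 * log(n))
  expect_equal(ebic_score(om, S, n, gamma = 0.5),
               -2 * L + log(n) + 4 * 0.5 * log(2))

  # an extra (numerically negligible) edge leaves the likelihood intact but
  # must cost a full penalty increment for gamma > 0
  S3 <- diag(3)
  om0 <- diag(3)
  om1 <- om0; om1[1, 2] <- om1[2, 1] <- 1e-6
  gap <- ebic_score(om1, S3, n, gamma = 0.5) -
    ebic_score(om0, S3, n, gamma = 0.5)
  expect_equal(gap, log(n) + 2 * log(3), tolerance = 1e-6)
})

test_that("identity input selects an empty network", {
  S <- diag(6)
  dimnames(S) <- list(letters[1:6], letters[1:6])
  net <- select_network(S, n = 100)
  expect_identical(net$edge_count, 0L)
  expect_true(all(net$weights == 0))
})

test_that("edge count is monotone along the penalty path", {
  net <- select_network(neck_pain_cor(), n = 100)
  ok <- !is.na(net$path$ebic)
  expect_true(all(diff(net$path$edge_count[ok]) >= 0))  # lambda descends
})

test_that("weights are valid partial correlations and satisfy the precision identity", {
  net <- neck_pain_network()
  expect_true(all(abs(net$weights) <= 1))
  expect_equal(diag(net$weights), setNames(rep(0, 6), net$node_labels))
  d <- 1 / sqrt(diag(net$precision))
  rebuilt <- -net$precision * outer(d, d); diag(rebuilt) <- 0
  expect_lt(max(abs(net$weights - rebuilt)), 1e-8)
  expect_gt(min(eigen(net$precision, only.values = TRUE)$values), 0)
})

test_that("partial correlations match the closed-form 3-variable oracle", {
  expect_true(all(partial_correlations(diag(c(2, 3, 4))) == 0))

  R <- rand_cor(3, seed = 4)
  w <- partial_correlations(solve(R))
  # residual-correlation oracle after regressing out the third variable
  oracle <- (R[1, 2] - R[1, 3] * R[2, 3]) /
    sqrt((1 - R[1, 3]^2) * (1 - R[2, 3]^2))
  expect_equal(w[1, 2], oracle, tolerance = 1e-6)

  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("a known sparse 6-node model is recovered from large samples", {
  mod <- known_sparse_model()
  set.seed(31)
  x <- MASS::mvrnorm(5000, rep(0, 6), mod$sigma)
  net <- select_network(cor(x), n = 5000, gamma = 0.5)
  est <- net$weights[upper.tri(net$weights)]
  expect_true(all(abs(est[mod$support]) > 1e-8))    # every true edge found
  # EBIC-glasso may keep a couple of numerically tiny spurious edges; any
  # false positive must be an order of magnitude below the weakest true edge
  expect_lte(sum(abs(est[!mod$support]) > 1e-8), 3)
  expect_lt(max(abs(est[!mod$support])), 0.05)
  truth <- mod$partial[upper.tri(mod$partial)]
  expect_gt(cor(truth[mod$support], est[mod$support]), 0.95)
})

test_that("quantile stratification exposes a common-effect reversal", {
  set.seed(5)
  n <- 20000
  x <- rnorm(n); y <- rnorm(n)
  c_ <- x + y + rnorm(n, sd = 0.3)
  tab <- data.frame(x = x, y = y, c = c_)
  dec <- simpson_decomposition(tab, "x", "y", "c")
  expect_lt(abs(dec$marginal), 0.03)          # marginally independent
  expect_true(all(dec$groups$r < -0.2))       # reversed within every stratum

  # independent conditioner: nothing happens
  tab2 <- data.frame(x = x, y = y, c = rnorm(n))
  dec2 <- simpson_decomposition(tab2, "x", "y", "c")
  expect_true(all(abs(dec2$groups$r) < 0.05))

  expect_error(simpson_decomposition(tab, "x", "y", "nope"), "unknown")
})

test_that("within-group correlations match the truncated-Gaussian oracle", {
  R <- matrix(c(1, 0.3, 0.5,
                0.3, 1, 0.6,
                0.5, 0.6, 1), 3, byrow = TRUE)
  set.seed(9)
  x <- MASS::mvrnorm(200000, rep(0, 3), R)
  tab <- data.frame(x = x[, 1], y = x[, 2], c = x[, 3])
  dec <- simpson_decomposition(tab, "x", "y", "c", n_groups = 3)
  cuts <- qnorm(c(0, 1 / 3, 2 / 3, 1))
  for (k in 1:3) {
    oracle <- cond_group_cor(R, cuts[k], cuts[k + 1])
    expect_lt(abs(dec$groups$r[k] - oracle), 0.02)
  }
})
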