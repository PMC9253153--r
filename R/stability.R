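#' Bootstrap / stability configuration
#'
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param drop_proportions Case-dropping grid (default 0.05 to 0.75 in
#'   steps of 0.05).
#' @param cor_threshold Correlation level defining stability (default 0.7).
#' @param confidence Required fraction of subsample correlations above the
#'   threshold (default 0.95, i.e. the 5th percentile rule).
#' @param seed Integer seed.
#' @return A `necknet_stability_config` list.
#' @export
stability_config <- function(n_boot = 1000,
                             drop_proportions = seq(0.05, 0.75, by = 0.05),
                             cor_threshold = 0.7, confidence = 0.95,
                             seed = 1L) {
  stopifnot(n_boot >= 1, all(drop_proportions > 0), all(drop_proportions < 1),
            cor_threshold > 0, cor_threshold < 1,
            confidence > 0, confidence < 1)
  structure(list(n_boot = as.integer(n_boot),
                 drop_proportions = sort(drop_proportions),
                 cor_threshold = cor_threshold, confidence = confidence,
                 seed = as.integer(seed)),
            class = "necknet_stability_config")
}

# One full network estimation from a raw feature table.
estimate_from_table <- function(table, gamma, path, npn = TRUE) {
  x <- if (npn) nonparanormal_transform(table) else as.data.frame(table)
  select_network(pearson_matrix(x)$r, n = nrow(table), gamma = gamma,
                 path = path)
}

#' Nonparametric bootstrap of edge weights
#'
#' Re-estimates the whole pipeline (nonparanormal transformation, Pearson
#' correlation, EBIC-glasso selection) on `n_boot` resamples of
#' participants drawn with replacement, and summarizes each edge with its
#' bootstrap mean and empirical 2.5 % / 97.5 % quantile bounds (for the
#' default 95 % confidence level). Resamples that produce a constant
#' column are redrawn.
#'
#' @param table Participant feature table.
#' @param config A [stability_config()].
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param path A [path_config()].
#' @param npn Apply the nonparanormal transformation (default `TRUE`).
#' @return A `necknet_edge_ci` list: `edges` (data frame with `node_a`,
#'   `node_b`, `weight`, `boot_mean`, `lower`, `upper`), `samples` (matrix
#'   of bootstrapped weights, one row per resample), `network` (the
#'   original fit), `config`.
#' @export
bootstrap_edges <- function(table, config = stability_config(),
                            gamma = 0.5, path = path_config(), npn = TRUE) {
  net <- estimate_from_table(table, gamma, path, npn)
  p <- length(net$node_labels)
  ut <- upper.tri(net$weights)
  pairs <- which(ut, arr.ind = TRUE)
  n <- nrow(table)
  alpha <- 1 - config$confidence

  samples <- matrix(NA_real_, config$n_boot, nrow(pairs))
  redraws <- 0L
  with_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        boot <- table[idx, , drop = FALSE]
        if (all(vapply(boot, function(col) sd(col) > 0, logical(1)))) break
        redraws <- redraws + 1L
        if (redraws > 100 * config$n_boot)
          stop("too many degenerate resamples")
      }
      bnet <- estimate_from_table(boot, gamma, path, npn)
      samples[b, ] <- bnet$weights[ut]
    }
  })
  if (redraws > 0)
    message(redraws, " degenerate resample(s) redrawn")

  edges <- data.frame(
    node_a = net$node_labels[pairs[, 1]],
    node_b = net$node_labels[pairs[, 2]],
    weight = net$weights[ut],
    boot_mean = colMeans(samples),
    lower = apply(samples, 2, quantile, probs = alpha / 2),
    upper = apply(samples, 2, quantile, probs = 1 - alpha / 2),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, samples = samples, network = net,
                 config = config),
            class = "necknet_edge_ci")
}

#' Case-dropping bootstrap of centrality indices
#'
#' For each drop proportion `p`, draws `n_boot` subsamples without
#' replacement of size `round((1 - p) n)`, re-estimates the network and
#' its centrality indices, and records the Pearson correlation between the
#' subsample and original centrality vectors (per index). Proportions
#' whose subsample would fall below `p_nodes + 2` cases are skipped with a
#' warning. Correlations that are undefined because a centrality vector is
#' constant (e.g. an empty network) are recorded as `NA`.
#'
#' @inheritParams bootstrap_edges
#' @return A `necknet_stability_curve` list: `curve` (data frame with
#'   `index`, `proportion`, `replicate`, `correlation`), `original`
#'   (centrality profile of the full sample), `config`.
#' @export
casedrop_bootstrap <- function(table, config = stability_config(),
                               gamma = 0.5, path = path_config(),
                               npn = TRUE) {
  net <- estimate_from_table(table, gamma, path, npn)
  orig <- centrality_profile(net)
  n <- nrow(table)
  p <- length(net$node_labels)
  indices <- c("strength", "closeness", "betweenness")

  rows <- list()
  with_seed(config$seed, {
    for (prop in config$drop_proportions) {
      n_sub <- round((1 - prop) * n)
      if (n_sub < p + 2) {
        warning("proportion ", prop, " skipped: subsample of ", n_sub,
                " cases is too small")
        next
      }
      for (b in seq_len(config$n_boot)) {
        idx <- sample.int(n, n_sub)
        sub <- table[idx, , drop = FALSE]
        cors <- rep(NA_real_, length(indices))
        ok <- all(vapply(sub, function(col) sd(col) > 0, logical(1)))
        if (ok) {
          cent <- centrality_profile(estimate_from_table(sub, gamma, path,
                                                         npn))
          for (k in seq_along(indices)) {
            a <- orig[[indices[k]]]; z <- cent[[indices[k]]]
            if (sd(a) > 0 && sd(z) > 0) cors[k] <- cor(a, z)
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          index = indices, proportion = prop, replicate = b,
          correlation = cors, stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(curve = do.call(rbind, rows), original = orig,
                 config = config),
            class = "necknet_stability_curve")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `p` in the grid such that, for every grid
#' proportion up to and including `p`, at least `confidence` of the
#' subsample-vs-original centrality correlations are at or above
#' `cor_threshold`. Returns 0 for an index that fails already at the
#' smallest proportion. Undefined (`NA`) correlations count as failures.
#'
#' @param curve A `necknet_stability_curve` from [casedrop_bootstrap()].
#' @param config A [stability_config()]; defaults to the curve's own.
#' @return Named numeric vector, one CS coefficient per centrality index.
#' @export
cs_coefficient <- function(curve, config = NULL) {
  stopifnot(inherits(curve, "necknet_stability_curve"))
  if (is.null(config)) config <- curve$config
  cv <- curve$curve
  props <- sort(unique(cv$proportion))
  if (length(props) < 3)
    stop("CS coefficient needs a curve over at least 3 proportions")
  indices <- unique(cv$index)
  out <- setNames(numeric(length(indices)), indices)
  for (ix in indices) {
    cs <- 0
    for (prop in props) {
      cc <- cv$correlation[cv$index == ix & cv$proportion == prop]
      frac <- mean(!is.na(cc) & cc >= config$cor_threshold)
      if (frac >= config$confidence) cs <- prop else break
    }
    out[ix] <- cs
  }
  out
}

#' Sample-size simulation for network replicability
#'
#' Treats a fitted network as the ground truth: for each candidate sample
#' size, draws Gaussian datasets from the model's implied correlation
#' structure (the standardized inverse precision matrix), re-estimates the
#' network, and reports the mean sensitivity (true edges recovered),
#' specificity (true zeros kept), and Pearson correlation between the true
#' and estimated edge-weight vectors.
#'
#' @param model A `necknet_network` used as the generating truth.
#' @param n_grid Sample sizes to simulate.
#' @param replicates Datasets per sample size (>= 10).
#' @param gamma,path Estimation settings for the re-fits.
#' @param seed Integer seed.
#' @return Data frame with one row per sample size: `n`, `sensitivity`,
#'   `specificity`, `weight_correlation`.
#' @export
sample_size_simulation <- function(model, n_grid = c(100, 250, 500, 1000),
                                   replicates = 20, gamma = 0.5,
                                   path = path_config(), seed = 1L) {
  stopifnot(inherits(model, "necknet_network"), replicates >= 10)
  sigma <- solve(model$precision)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("implied covariance is singular")
  sigma <- stats::cov2cor(sigma)
  true_w <- model$weights[upper.tri(model$weights)]
  true_edge <- abs(true_w) > 1e-8

  with_seed(seed, {
    out <- lapply(n_grid, function(n) {
      sens <- spec <- wcor <- numeric(replicates)
      for (r in seq_len(replicates)) {
        x <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
        net <- select_network(cor(x), n = n, gamma = gamma, path = path)
        est_w <- net$weights[upper.tri(net$weights)]
        est_edge <- abs(est_w) > 1e-8
        sens[r] <- if (any(true_edge)) mean(est_edge[true_edge]) else NA
        spec[r] <- if (any(!true_edge)) mean(!est_edge[!true_edge]) else NA
        wcor[r] <- if (sd(true_w) > 0 && sd(est_w) > 0)
          cor(true_w, est_w) else NA
      }
      data.frame(n = n, sensitivity = mean(sens), specificity = mean(spec),
                 weight_correlation = mean(wcor, na.rm = TRUE))
    })
    do.call(rbind, out)
  })
}
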