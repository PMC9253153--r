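#' Canonical node order of the neck-pain feature network
#'
#' The six network nodes, in the order used throughout the package: Tampa
#' Scale for Kinesiophobia total score (TSK), joint position error (JPE,
#' degrees), range of motion (ROM, degrees), mean angular velocity
#' (Velocity, deg/s), spectral arc length smoothness (SPARC, dimensionless,
#' negative), and peak isometric neck strength (Strength, newtons).
#'
#' @return Character vector of length 6.
#' @export
neck_feature_names <- function() {
  c("TSK", "JPE", "ROM", "Velocity", "SPARC", "Strength")
}

#' Published Pearson correlation matrix of the six neck-pain features
#'
#' The pairwise Pearson correlations between the six features as reported for
#' the 100-participant neck-pain cohort (printed to two decimals). The matrix
#' is symmetric with unit diagonal and is positive definite (smallest
#' eigenvalue 0.256), so it can be fed directly to [select_network()].
#'
#' @return A 6x6 named correlation matrix in [neck_feature_names()] order.
#' @export
#' @examples
#' S <- neck_pain_cor()
#' eigen(S, only.values = TRUE)$values
neck_pain_cor <- function() {
  labs <- neck_feature_names()
  S <- diag(6)
  dimnames(S) <- list(labs, labs)
  # upper triangle, column-major == printed lower triangle read row by row
  S[upper.tri(S)] <- c(
     0.16,
    -0.24, -0.01,
    -0.27,  0.18, 0.46,
    -0.21,  0.16, 0.14, 0.65,
    -0.19,  0.24, 0.07, 0.20, 0.08)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Reference cohort marginals for the six features
#'
#' Mean and standard deviation of each feature in the neck-pain history
#' cohort (n = 85 of the 100 assessed participants): TSK 35.0 +- 6.4,
#' JPE 6.1 +- 3.7 deg, ROM 49.7 +- 6.7 deg, velocity 61.6 +- 20.3 deg/s,
#' SPARC -1.68 +- 0.11, strength 81.8 +- 30.7 N. These are the default
#' marginals of [cohort_spec()]. Set `history = FALSE` for the
#' no-history group (n = 15).
#'
#' @param history Logical; use the history-of-neck-pain column (default) or
#'   the no-history column.
#' @return Data frame with columns `feature`, `mean`, `sd`.
#' @export
neck_pain_marginals <- function(history = TRUE) {
  if (history) {
    data.frame(
      feature = neck_feature_names(),
      mean = c(35.0, 6.10, 49.7, 61.6, -1.68, 81.8),
      sd   = c(6.4, 3.70, 6.7, 20.3, 0.11, 30.7),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      feature = neck_feature_names(),
      mean = c(29.3, 7.00, 53.0, 76.7, -1.61, 108.5),
      sd   = c(4.4, 4.50, 6.8, 21.5, 0.08, 56.38),
      stringsAsFactors = FALSE)
  }
}

#' Re-estimate the published neck-pain network from the printed correlations
#'
#' Convenience wrapper: runs EBIC-glasso network selection on the printed
#' correlation matrix ([neck_pain_cor()]) with the published sample size
#' (n = 100). The published analysis was deliberately exploratory, which
#' corresponds to the EBIC hyperparameter `gamma = 0` (plain BIC); with that
#' setting 12 of the 15 possible edges are retained and the strong
#' kinematic edges (ROM-Velocity, Velocity-SPARC) match the published
#' weights to within printed rounding. `gamma = 0.5` (the conservative
#' default elsewhere in the package) prunes the network down to the two
#' strongest kinematic edges.
#'
#' @param gamma EBIC hyperparameter; 0 reproduces the published network.
#' @param n Sample size behind the correlation matrix.
#' @param ... Passed on to [select_network()].
#' @return A `necknet_network` object (see [select_network()]).
#' @export
#' @examples
#' net <- neck_pain_network()
#' net$edge_count
#' round(net$weights["ROM", "Velocity"], 2)
neck_pain_network <- function(gamma = 0, n = 100, ...) {
  select_network(neck_pain_cor(), n = n, gamma = gamma, ...)
}
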