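#' Descriptive summary of a feature table
#'
#' Mean and standard deviation per feature, optionally split by a grouping
#' vector. The SD of a single-participant group is reported as `NA`.
#'
#' @param table Participant feature table.
#' @param grouping Optional vector of group labels, one per participant.
#' @return Data frame with columns `group` (if grouping), `feature`,
#'   `mean`, `sd`, `n`.
#' @export
descriptive_summary <- function(table, grouping = NULL) {
  table <- as.data.frame(table)
  if (is.null(grouping)) grouping <- rep("all", nrow(table))
  if (length(grouping) != nrow(table))
    stop("grouping must have one label per participant")
  out <- do.call(rbind, lapply(split(seq_len(nrow(table)), grouping),
    function(idx) {
      data.frame(group = grouping[idx[1]],
                 feature = names(table),
                 mean = vapply(table[idx, , drop = FALSE], mean, numeric(1)),
                 sd = if (length(idx) > 1)
                   vapply(table[idx, , drop = FALSE], sd, numeric(1))
                 else NA_real_,
                 n = length(idx),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Run the end-to-end network analysis
#'
#' Orchestrates the full analysis in one of three input modes:
#'
#' * `"raw-signals"`: per-participant recordings (movement waveforms,
#'   relocation trials, strength peaks, TSK) are reduced to the six-node
#'   feature table with [extract_participant_features()], then analysed as
#'   below.
#' * `"feature-table"`: the feature table is summarized, nonparanormal-
#'   transformed, correlated, and the EBIC-glasso network, centrality, and
#'   (optionally) bootstrap stability are computed.
#' * `"correlation-matrix"`: a printed Pearson matrix plus its sample size
#'   are fed directly to network selection (no transformation, no
#'   bootstrap), which reproduces published results when raw data are
#'   unavailable.
#'
#' @param mode Input mode (see above).
#' @param feature_table Feature table (modes `feature-table`).
#' @param cor_matrix Correlation matrix (mode `correlation-matrix`).
#' @param n Sample size behind `cor_matrix`.
#' @param recordings List of participants (mode `raw-signals`), as produced
#'   by [generate_cohort_recordings()].
#' @param gamma EBIC hyperparameter (default 0.5; use 0 for the
#'   exploratory selection that reproduces the published network).
#' @param path A [path_config()].
#' @param npn Apply the nonparanormal transformation (default `TRUE`).
#' @param stability `NULL` to skip bootstrapping, or a
#'   [stability_config()] to compute edge CIs, case-dropping curves, and
#'   CS coefficients.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   are written as delimited text plus a JSON report.
#' @param seed Seed recorded in the provenance block and used for the
#'   stability stage when its config carries none.
#' @return A `necknet_report` list with `descriptives`, `pearson`,
#'   `network`, `centrality`, `stability`, and `provenance`.
#' @export
#' @examples
#' rep <- run_pipeline("correlation-matrix", cor_matrix = neck_pain_cor(),
#'                     n = 100, gamma = 0)
#' rep$network$edge_count
run_pipeline <- function(mode = c("feature-table", "correlation-matrix",
                                  "raw-signals"),
                         feature_table = NULL, cor_matrix = NULL, n = NULL,
                         recordings = NULL, gamma = 0.5,
                         path = path_config(), npn = TRUE,
                         stability = NULL, out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  descriptives <- NULL
  pearson <- NULL

  if (mode == "raw-signals") {
    if (is.null(recordings)) stop("raw-signals mode needs `recordings`")
    message("extracting features from ", length(recordings),
            " participants")
    feature_table <- do.call(rbind,
      lapply(recordings, extract_participant_features))
    mode <- "feature-table"
  }

  if (mode == "feature-table") {
    if (is.null(feature_table)) stop("feature-table mode needs a table")
    feature_table <- as.data.frame(feature_table)
    if (anyNA(feature_table)) {
      keep <- complete.cases(feature_table)
      message("dropping ", sum(!keep), " incomplete case(s)")
      feature_table <- feature_table[keep, , drop = FALSE]
    }
    n <- nrow(feature_table)
    descriptives <- descriptive_summary(feature_table)
    analysed <- if (npn) nonparanormal_transform(feature_table)
                else feature_table
    pearson <- pearson_matrix(analysed)
    S <- pearson$r
  } else {
    if (is.null(cor_matrix) || is.null(n))
      stop("correlation-matrix mode needs `cor_matrix` and `n`")
    S <- cor_matrix
    if (!is.null(stability))
      stop("bootstrap stability needs raw data, not a printed matrix")
  }

  network <- select_network(S, n = n, gamma = gamma, path = path)
  centrality <- centrality_profile(network)

  stab <- NULL
  if (!is.null(stability)) {
    stopifnot(inherits(stability, "necknet_stability_config"))
    message("bootstrapping edges (", stability$n_boot, " resamples)")
    eci <- bootstrap_edges(feature_table, stability, gamma = gamma,
                           path = path, npn = npn)
    message("case-dropping bootstrap")
    curve <- casedrop_bootstrap(feature_table, stability, gamma = gamma,
                                path = path, npn = npn)
    stab <- list(edge_ci = eci, curve = curve,
                 cs = cs_coefficient(curve))
  }

  report <- structure(list(
    descriptives = descriptives,
    pearson = pearson,
    network = network,
    centrality = centrality,
    stability = stab,
    provenance = list(mode = if (is.null(feature_table))
                        "correlation-matrix" else "feature-table",
                      n = n, gamma = gamma,
                      n_lambdas = path$n_lambdas,
                      lambda_min_ratio = path$lambda_min_ratio,
                      npn = npn, seed = seed,
                      version = as.character(utils::packageVersion("necknet")))),
    class = "necknet_report")

  if (!is.null(out_dir)) write_report(report, feature_table, out_dir)
  report
}

write_report <- function(report, feature_table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  if (!is.null(feature_table))
    write_feature_table(feature_table, fp("feature_table.csv"))
  if (!is.null(report$descriptives))
    write.csv(report$descriptives, fp("descriptives.csv"), row.names = FALSE)
  if (!is.null(report$pearson))
    write_square_matrix(report$pearson$r, fp("pearson.csv"))
  write_square_matrix(report$network$weights, fp("weights.csv"))
  write_edge_list(report$network, fp("edges.csv"))
  write.csv(report$centrality, fp("centrality.csv"), row.names = FALSE)
  if (!is.null(report$stability)) {
    write.csv(report$stability$edge_ci$edges, fp("edge_ci.csv"),
              row.names = FALSE)
    write.csv(report$stability$curve$curve, fp("stability_curve.csv"),
              row.names = FALSE)
    write.csv(data.frame(index = names(report$stability$cs),
                         cs = unname(report$stability$cs)),
              fp("cs_coefficients.csv"), row.names = FALSE)
  }
  json <- list(
    provenance = report$provenance,
    edge_count = report$network$edge_count,
    lambda = report$network$lambda,
    ebic = report$network$ebic,
    weights = as.data.frame(report$network$weights),
    centrality = report$centrality)
  if (!is.null(report$stability))
    json$cs <- as.list(report$stability$cs)
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.necknet_report <- function(x, ...) {
  cat("necknet analysis report (n = ", x$provenance$n, ", mode = ",
      x$provenance$mode, ")\n\n", sep = "")
  print(x$network)
  cat("\nCentrality:\n")
  print(x$centrality, row.names = FALSE)
  if (!is.null(x$stability)) {
    cat("\nCS coefficients:\n")
    print(x$stability$cs)
  }
  invisible(x)
}
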