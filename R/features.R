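#' Joint reposition error from marked relocation trials
#'
#' Mean over trials of the absolute angle difference between each trial's
#' end and start marker samples (the proprioception proxy of the
#' cervicocephalic relocation test).
#'
#' @param trials List of exactly 6 trials, each with `waveform`,
#'   `start_marker`, `end_marker` (as produced by
#'   [generate_relocation_trials()]).
#' @return Degrees (nonnegative scalar).
#' @export
#' @examples
#' trials <- generate_relocation_trials(relocation_spec(c(3, -5, 7, -2, 4, -9)))
#' joint_reposition_error(trials)  # 5
joint_reposition_error <- function(trials) {
  if (length(trials) != 6)
    stop("exactly 6 relocation trials are required, got ", length(trials))
  errs <- vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (is.null(tr$start_marker) || is.null(tr$end_marker))
      stop("trial ", i, " is missing a start or end marker")
    th <- tr$waveform$samples
    if (tr$start_marker < 1 || tr$end_marker > length(th))
      stop("trial ", i, " markers outside the waveform")
    abs(th[tr$end_marker] - th[tr$start_marker])
  }, numeric(1))
  mean(errs)
}

#' Assemble one participant's six-node feature record
#'
#' Kinematic nodes are unweighted means over the six movement directions;
#' the strength node is the mean of the flexion and extension peak forces.
#'
#' @param directional Data frame with columns `direction`, `rom_deg`,
#'   `mean_velocity_deg_s`, `sparc` holding one (already cycle-averaged)
#'   value per movement direction; all six directions must be present.
#' @param strength_flexion_n,strength_extension_n MVC peak forces, newtons.
#' @param jpe_deg Joint reposition error, degrees.
#' @param tsk TSK questionnaire total (17-68).
#' @return One-row data frame with columns `TSK`, `JPE`, `ROM`, `Velocity`,
#'   `SPARC`, `Strength`.
#' @export
aggregate_features <- function(directional, strength_flexion_n,
                               strength_extension_n, jpe_deg, tsk) {
  expected <- c("flexion", "extension", "rotation_right", "rotation_left",
                "lateral_right", "lateral_left")
  missing_dir <- setdiff(expected, directional$direction)
  if (length(missing_dir) > 0)
    stop("missing movement direction(s): ",
         paste(missing_dir, collapse = ", "))
  sel <- directional$direction %in% expected
  data.frame(
    TSK = tsk,
    JPE = jpe_deg,
    ROM = mean(directional$rom_deg[sel]),
    Velocity = mean(directional$mean_velocity_deg_s[sel]),
    SPARC = mean(directional$sparc[sel]),
    Strength = (strength_flexion_n + strength_extension_n) / 2)
}

#' Extract a participant's feature record from raw recordings
#'
#' Runs [extract_waveform_features()] on each movement-plane recording,
#' averages each kinematic feature over the cycles of every direction,
#' computes the joint reposition error from the relocation trials, and
#' assembles the six-node record with [aggregate_features()].
#'
#' @param participant List with `waveforms` (three `necknet_waveform`s),
#'   `trials`, `strength_flexion_n`, `strength_extension_n`, `tsk` (as
#'   produced by [generate_cohort_recordings()]).
#' @param ... Passed to [extract_waveform_features()].
#' @return One-row feature data frame.
#' @export
extract_participant_features <- function(participant, ...) {
  mv <- do.call(rbind, lapply(participant$waveforms, function(w)
    extract_waveform_features(w, ...)$movements))
  if (is.null(mv) || nrow(mv) == 0) stop("no movements extracted")
  directional <- do.call(rbind, lapply(split(mv, mv$direction), function(d)
    data.frame(direction = d$direction[1],
               rom_deg = mean(d$rom_deg),
               mean_velocity_deg_s = mean(d$mean_velocity_deg_s),
               sparc = mean(d$sparc), stringsAsFactors = FALSE)))
  aggregate_features(directional,
                     participant$strength_flexion_n,
                     participant$strength_extension_n,
                     joint_reposition_error(participant$trials),
                     participant$tsk)
}

#' Truncation constant of the nonparanormal transformation
#'
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, the standard truncation
#' level for the empirical CDF before the normal-quantile map.
#'
#' @param n Sample size (>= 2).
#' @return Value in (0, 0.5).
#' @export
npn_delta <- function(n) {
  stopifnot(n >= 2)
  1 / (4 * n^0.25 * sqrt(pi * log(n)))
}

#' Nonparanormal (Gaussian copula) transformation of a feature table
#'
#' Column-wise rank-based Gaussianization: the empirical CDF (average ranks
#' for ties, divided by n) is truncated to `[delta, 1 - delta]`, mapped
#' through the standard-normal quantile function, and rescaled to unit
#' sample standard deviation. The transform preserves each column's rank
#' order exactly, so Spearman correlations are unchanged.
#'
#' @param table Data frame or matrix of numeric features (n >= 4 rows, no
#'   missing values).
#' @param delta Truncation constant; default [npn_delta()] of the row
#'   count.
#' @return Data frame of transformed features.
#' @export
#' @examples
#' tab <- generate_feature_table(cohort_spec(n = 50))
#' round(colMeans(nonparanormal_transform(tab)), 3)
nonparanormal_transform <- function(table, delta = NULL) {
  x <- as.data.frame(table)
  n <- nrow(x)
  if (n < 4) stop("nonparanormal transformation needs n >= 4")
  if (anyNA(x)) stop("missing values are not allowed")
  if (is.null(delta)) delta <- npn_delta(n)
  stopifnot(delta > 0, delta < 0.5)
  for (j in seq_along(x)) {
    if (sd(x[[j]]) == 0)
      stop("constant column: ", names(x)[j])
    u <- rank(x[[j]], ties.method = "average") / n
    z <- qnorm(pmin(pmax(u, delta), 1 - delta))
    x[[j]] <- z / sd(z)
  }
  x
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations with two-sided t-distribution p-values and
#' the conventional per-pair flags (`*` for p <= .05, `**` for p < .01, no
#' multiplicity correction).
#'
#' @param table Data frame or matrix of numeric features (n >= 4).
#' @return A `necknet_cor` list: `r` (correlation matrix), `p` (p-value
#'   matrix), `stars` (character matrix), `n`.
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(as.data.frame(table))
  n <- nrow(x)
  if (n < 4) stop("need at least 4 cases")
  if (any(apply(x, 2, sd) == 0))
    stop("constant column: ",
         paste(colnames(x)[apply(x, 2, sd) == 0], collapse = ", "))
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p <= 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n), class = "necknet_cor")
}

#' @export
print.necknet_cor <- function(x, digits = 2, ...) {
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  diag(m) <- "-"
  print(m, quote = FALSE)
  cat("n =", x$n, "  * p <= .05, ** p < .01\n")
  invisible(x)
}
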