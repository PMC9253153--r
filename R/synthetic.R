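#' Specification of a synthetic participant cohort
#'
#' Describes the cohort whose feature table [generate_feature_table()]
#' draws: per-feature marginal means and SDs, a target Pearson correlation
#' matrix, and optional strictly monotone marginal distortions that induce
#' realistic non-Gaussian marginals (applied after correlating, so the rank
#' structure of the table is preserved). Defaults reproduce the neck-pain
#' history cohort: marginals from [neck_pain_marginals()], correlations
#' from [neck_pain_cor()], a right-skewed (shifted exponential) joint
#' position error, and integer-rounded TSK scores clamped to the 17-68
#' questionnaire range.
#'
#' @param n Number of participants (default 100, the analysed sample).
#' @param feature_names Feature labels, default [neck_feature_names()].
#' @param marginal_means,marginal_sds Numeric vectors, one entry per feature.
#' @param target_correlation Symmetric positive-definite correlation matrix.
#' @param marginal_distortions Named list of strictly monotone functions
#'   applied to the scaled columns; `NULL` entries leave a column Gaussian.
#'   Use `list()` for fully Gaussian marginals.
#' @param seed Integer seed for reproducibility.
#' @return A `necknet_cohort_spec` list.
#' @export
cohort_spec <- function(n = 100,
                        feature_names = neck_feature_names(),
                        marginal_means = NULL,
                        marginal_sds = NULL,
                        target_correlation = NULL,
                        marginal_distortions = NULL,
                        seed = 1L) {
  p <- length(feature_names)
  marg <- neck_pain_marginals()
  if (is.null(marginal_means))
    marginal_means <- marg$mean[match(feature_names, marg$feature)]
  if (is.null(marginal_sds))
    marginal_sds <- marg$sd[match(feature_names, marg$feature)]
  if (is.null(target_correlation)) {
    if (identical(feature_names, neck_feature_names())) {
      target_correlation <- neck_pain_cor()
    } else {
      target_correlation <- diag(p)
      dimnames(target_correlation) <- list(feature_names, feature_names)
    }
  }
  if (is.null(marginal_distortions))
    marginal_distortions <- default_distortions(feature_names,
                                                marginal_means, marginal_sds)
  stopifnot(n >= 1, length(marginal_means) == p, length(marginal_sds) == p)
  if (any(is.na(marginal_means)) || any(is.na(marginal_sds)))
    stop("marginal means/sds missing for some features")
  if (any(marginal_sds <= 0)) stop("marginal_sds must be positive")
  if (nrow(target_correlation) != p || ncol(target_correlation) != p)
    stop("target_correlation must be ", p, "x", p)
  if (max(abs(target_correlation - t(target_correlation))) > 1e-10)
    stop("target_correlation must be symmetric")
  if (max(abs(diag(target_correlation) - 1)) > 1e-10)
    stop("target_correlation must have a unit diagonal")
  if (any(abs(target_correlation) > 1))
    stop("correlations must lie in [-1, 1]")
  ev <- eigen(target_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("target_correlation is not positive definite; smallest eigenvalue ",
         format(min(ev), digits = 4))

  structure(list(n = as.integer(n), feature_names = feature_names,
                 marginal_means = marginal_means, marginal_sds = marginal_sds,
                 target_correlation = target_correlation,
                 marginal_distortions = marginal_distortions,
                 seed = as.integer(seed)),
            class = "necknet_cohort_spec")
}

# Default non-Gaussian marginals: right-skewed JPE (shifted exponential with
# the requested mean and SD) and integer TSK scores on the 17-68 scale.
default_distortions <- function(feature_names, means, sds) {
  d <- list()
  if ("JPE" %in% feature_names) {
    i <- match("JPE", feature_names)
    m <- means[i]; s <- sds[i]
    d$JPE <- function(x) m - s + s * qexp(pnorm((x - m) / s))
  }
  if ("TSK" %in% feature_names)
    d$TSK <- function(x) pmin(68, pmax(17, round(x)))
  d
}

#' Generate a correlated synthetic feature table
#'
#' Draws `n` participants with the target Pearson correlation structure by
#' mixing independent standard normals through the Cholesky factor of the
#' target matrix, scales each column to its marginal mean and SD, and then
#' applies the spec's monotone marginal distortions. Positive-valued
#' physical features (ROM, Velocity, Strength, JPE) are floored at 0.1 to
#' keep rare extreme Gaussian draws physically meaningful.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `n` rows and one column per feature.
#' @export
#' @examples
#' tab <- generate_feature_table(cohort_spec(n = 200, seed = 42))
#' round(cor(tab)["Velocity", "SPARC"], 2)
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "necknet_cohort_spec"))
  p <- length(spec$feature_names)
  with_seed(spec$seed, {
    Z <- matrix(rnorm(spec$n * p), spec$n, p)
    Z <- Z %*% chol(spec$target_correlation)
    X <- sweep(sweep(Z, 2, spec$marginal_sds, "*"), 2,
               spec$marginal_means, "+")
    colnames(X) <- spec$feature_names
    X <- as.data.frame(X)
    for (nm in names(spec$marginal_distortions)) {
      f <- spec$marginal_distortions[[nm]]
      if (!is.null(f) && nm %in% names(X)) X[[nm]] <- f(X[[nm]])
    }
    for (nm in intersect(c("ROM", "Velocity", "Strength", "JPE"), names(X)))
      X[[nm]] <- pmax(X[[nm]], 0.1)
    X
  })
}

#' Specification of one cyclic neck-movement recording
#'
#' Parameters of a synthetic joint-angle waveform for one movement plane:
#' sinusoidal cycles spanning -`rom_deg` .. +`rom_deg` (raised-cosine
#' half-cycles between the two end-ranges), with the cycle period chosen so
#' the noise-free mean angular speed equals `mean_velocity_deg_s`.
#' Reduced smoothness is emulated with band-limited (8-15 Hz) additive
#' angular noise whose RMS amplitude in degrees is
#' `jerk_noise_amplitude`; self-paced timing variability is a per-cycle
#' period jitter with coefficient of variation `cycle_cv`.
#'
#' @param plane One of `"flexion-extension"`, `"rotation"`,
#'   `"lateral-flexion"`.
#' @param n_cycles Number of movement cycles (default 10).
#' @param rom_deg Peak excursion from neutral, degrees.
#' @param mean_velocity_deg_s Target mean absolute angular speed, deg/s.
#' @param jerk_noise_amplitude RMS amplitude (degrees) of the 8-15 Hz
#'   noise; 0.2 yields smoothness (SPARC) near -1.7 after standard
#'   extraction, 0 gives an infinitely differentiable profile.
#' @param cycle_cv Coefficient of variation of per-cycle periods (default
#'   0.05; set 0 for perfectly periodic cycles).
#' @param lead_in_s Neutral rest recorded before movement onset, seconds
#'   (default 1; the extraction pipeline uses the start of the recording
#'   as its neutral reference).
#' @param fs_hz Sampling rate (default 100).
#' @param seed Integer seed.
#' @return A `necknet_movement_profile` list.
#' @export
movement_profile <- function(plane = "flexion-extension", n_cycles = 10,
                             rom_deg = 49.7, mean_velocity_deg_s = 61.6,
                             jerk_noise_amplitude = 0.2, cycle_cv = 0.05,
                             lead_in_s = 1, fs_hz = 100, seed = 1L) {
  plane <- match.arg(plane,
                     c("flexion-extension", "rotation", "lateral-flexion"))
  stopifnot(n_cycles >= 1, rom_deg > 0, mean_velocity_deg_s > 0,
            jerk_noise_amplitude >= 0, cycle_cv >= 0, lead_in_s >= 0,
            fs_hz > 0)
  structure(list(plane = plane, n_cycles = as.integer(n_cycles),
                 rom_deg = rom_deg,
                 mean_velocity_deg_s = mean_velocity_deg_s,
                 jerk_noise_amplitude = jerk_noise_amplitude,
                 cycle_cv = cycle_cv, lead_in_s = lead_in_s, fs_hz = fs_hz,
                 seed = as.integer(seed)),
            class = "necknet_movement_profile")
}

# Unit-RMS Gaussian noise band-limited to [lo, hi] Hz by FFT masking.
band_limited_noise <- function(n, fs, lo = 8, hi = 15) {
  hi <- min(hi, 0.45 * fs)
  z <- rnorm(n)
  Z <- fft(z)
  f <- (seq_len(n) - 1) * fs / n
  fa <- pmin(f, fs - f)
  Z[!(fa >= lo & fa <= hi)] <- 0
  x <- Re(fft(Z, inverse = TRUE)) / n
  if (sd(x) == 0) return(rep(0, n))
  x / sd(x)
}

#' Generate a cyclic joint-angle waveform
#'
#' The recording starts with a neutral rest (`lead_in_s`), ramps smoothly
#' to the first end-range, and then oscillates between the two end-ranges
#' (`+rom_deg` and `-rom_deg`) with raised-cosine half-cycles, so every
#' extremum equals the requested range of motion exactly and every
#' extremum-to-extremum movement has a single smooth speed bump. The cycle
#' period is `T = 4 * rom_deg / mean_velocity_deg_s`, which makes the
#' noise-free mean angular speed of each movement equal to the requested
#' value. Per-cycle period jitter (`cycle_cv`) and band-limited angular
#' noise (`jerk_noise_amplitude`) are applied on top.
#'
#' @param profile A [movement_profile()].
#' @return A `necknet_waveform` (see [angle_waveform()]).
#' @export
#' @examples
#' w <- generate_angle_waveform(movement_profile(rom_deg = 50,
#'   jerk_noise_amplitude = 0, cycle_cv = 0))
#' max(w$samples)
generate_angle_waveform <- function(profile) {
  stopifnot(inherits(profile, "necknet_movement_profile"))
  fs <- profile$fs_hz
  rom <- profile$rom_deg
  T0 <- 4 * rom / profile$mean_velocity_deg_s
  if (T0 * fs < 10)
    stop("requested velocity/ROM imply a cycle of ",
         round(T0 * fs, 1), " samples; at least 10 are required")
  with_seed(profile$seed, {
    periods <- T0 * pmax(0.2, 1 + profile$cycle_cv * rnorm(profile$n_cycles))
    # target level and duration of each raised-cosine transition
    targets <- c(rom)
    durs <- c(periods[1] / 4)
    if (profile$n_cycles > 1) {
      for (k in 2:profile$n_cycles) {
        targets <- c(targets, -rom, rom)
        durs <- c(durs, periods[k] / 2, periods[k] / 2)
      }
    }
    targets <- c(targets, -rom, 0)
    durs <- c(durs, periods[profile$n_cycles] / 2,
              periods[profile$n_cycles] / 4)

    th <- rep(0, max(1, round(profile$lead_in_s * fs)))
    level <- 0
    for (i in seq_along(targets)) {
      m <- max(3L, round(durs[i] * fs))
      u <- (1:m) / m
      th <- c(th, level + (targets[i] - level) * (1 - cos(pi * u)) / 2)
      level <- targets[i]
    }
    if (profile$jerk_noise_amplitude > 0)
      th <- th + profile$jerk_noise_amplitude *
        band_limited_noise(length(th), fs)
    angle_waveform(th, fs_hz = fs, plane = profile$plane)
  })
}

#' Specification of a set of head-relocation (repositioning) trials
#'
#' Six trials of the cervicocephalic relocation test: full rotation from a
#' neutral start, alternating right and left, returning to neutral with a
#' signed repositioning error. The angle difference between the end and
#' start marker samples equals each requested error exactly.
#'
#' @param true_errors_deg Exactly 6 signed errors in degrees (3 per side).
#' @param rotation_amplitude_deg Rotation amplitude, degrees (default 70).
#' @param fs_hz Sampling rate (default 100).
#' @param seed Integer seed (reserved for optional noise).
#' @param noise_sd_deg SD of additive measurement noise on the movement
#'   portion of the waveform (markers stay exact); default 0.
#' @return A `necknet_relocation_spec` list.
#' @export
relocation_spec <- function(true_errors_deg, rotation_amplitude_deg = 70,
                            fs_hz = 100, seed = 1L, noise_sd_deg = 0) {
  if (length(true_errors_deg) != 6)
    stop("exactly 6 relocation errors are required, got ",
         length(true_errors_deg))
  stopifnot(rotation_amplitude_deg > 0, fs_hz > 0, noise_sd_deg >= 0)
  structure(list(true_errors_deg = as.numeric(true_errors_deg),
                 rotation_amplitude_deg = rotation_amplitude_deg,
                 fs_hz = fs_hz, seed = as.integer(seed),
                 noise_sd_deg = noise_sd_deg),
            class = "necknet_relocation_spec")
}

#' Generate marked head-relocation trial waveforms
#'
#' @param spec A [relocation_spec()].
#' @return List of 6 trials; each has `waveform` (a `necknet_waveform` of
#'   the rotation plane), `start_marker` and `end_marker` (sample indices),
#'   `side`, and `true_error_deg`.
#' @export
#' @examples
#' trials <- generate_relocation_trials(relocation_spec(c(3, -5, 7, -2, 4, -9)))
#' joint_reposition_error(trials)
generate_relocation_trials <- function(spec) {
  stopifnot(inherits(spec, "necknet_relocation_spec"))
  fs <- spec$fs_hz
  ramp <- function(from, to, dur) {
    m <- max(2, round(dur * fs))
    from + (to - from) * (1 - cos(pi * (0:(m - 1)) / (m - 1))) / 2
  }
  with_seed(spec$seed, {
    lapply(seq_along(spec$true_errors_deg), function(i) {
      err <- spec$true_errors_deg[i]
      side <- if (i %% 2 == 1) "right" else "left"
      amp <- spec$rotation_amplitude_deg * if (side == "right") 1 else -1
      hold0 <- rep(0, round(1.0 * fs))
      out <- ramp(0, amp, 1.5)
      holdT <- rep(amp, round(0.5 * fs))
      back <- ramp(amp, err, 1.5)
      hold1 <- rep(err, round(1.0 * fs))
      th <- c(hold0, out, holdT, back, hold1)
      if (spec$noise_sd_deg > 0) {
        i0 <- length(hold0); i1 <- length(th) - length(hold1)
        th[(i0 + 1):i1] <- th[(i0 + 1):i1] +
          rnorm(i1 - i0, sd = spec$noise_sd_deg)
      }
      list(waveform = angle_waveform(th, fs_hz = fs, plane = "rotation"),
           start_marker = round(0.5 * fs),
           end_marker = length(th) - round(0.5 * fs),
           side = side,
           true_error_deg = err)
    })
  })
}

# Approximate inverse of the jerk-noise -> SPARC response of the default
# movement profile under standard extraction (10 Hz zero-phase filtering,
# 5 % segmentation). Piecewise-linear, calibrated once on the default
# profile; used only to give cohort recordings roughly the requested
# smoothness.
sparc_to_jerk_noise <- function(sparc) {
  x <- c(-2.20, -2.00, -1.90, -1.80, -1.70, -1.62, -1.57, -1.50)
  y <- c(0.50, 0.33, 0.28, 0.24, 0.20, 0.15, 0.08, 0.02)
  stats::approx(x, y, xout = sparc, rule = 2)$y
}

#' Generate raw recordings for a whole synthetic cohort
#'
#' Expands a participant feature table into the raw material the
#' full extraction pipeline consumes: three cyclic movement recordings per
#' participant (one per plane, driven by the participant's ROM and
#' velocity, with jerk noise set from the participant's SPARC via a fixed
#' calibration curve), six marked relocation trials whose mean absolute
#' error equals the participant's JPE, and flexion/extension peak-force
#' values whose mean equals the participant's strength.
#'
#' @param table Feature table, e.g. from [generate_feature_table()].
#' @param n_cycles Cycles per movement plane (default 10).
#' @param fs_hz Sampling rate (default 100).
#' @param cycle_cv Per-cycle period jitter (default 0.05).
#' @param seed Integer seed.
#' @return List of participants; each has `waveforms` (named list of three
#'   `necknet_waveform`s), `trials`, `strength_flexion_n`,
#'   `strength_extension_n`, and `tsk`.
#' @export
generate_cohort_recordings <- function(table, n_cycles = 10, fs_hz = 100,
                                       cycle_cv = 0.05, seed = 1L) {
  needed <- c("TSK", "JPE", "ROM", "Velocity", "SPARC", "Strength")
  if (!all(needed %in% names(table)))
    stop("table must contain columns ", paste(needed, collapse = ", "))
  planes <- c("flexion-extension", "rotation", "lateral-flexion")
  with_seed(seed, {
    lapply(seq_len(nrow(table)), function(i) {
      row <- table[i, ]
      noise <- sparc_to_jerk_noise(row$SPARC)
      waves <- lapply(seq_along(planes), function(k) {
        generate_angle_waveform(movement_profile(
          plane = planes[k], n_cycles = n_cycles, rom_deg = row$ROM,
          mean_velocity_deg_s = row$Velocity,
          jerk_noise_amplitude = noise, cycle_cv = cycle_cv, fs_hz = fs_hz,
          seed = sample.int(.Machine$integer.max %/% 2, 1)))
      })
      names(waves) <- planes
      z <- rnorm(6)
      errs <- z * row$JPE / mean(abs(z))
      trials <- generate_relocation_trials(relocation_spec(
        errs, fs_hz = fs_hz,
        seed = sample.int(.Machine$integer.max %/% 2, 1)))
      ratio <- 0.7 + runif(1, -0.05, 0.05)  # flexion/extension force ratio
      list(waveforms = waves, trials = trials,
           strength_flexion_n = row$Strength * 2 * ratio / (1 + ratio),
           strength_extension_n = row$Strength * 2 / (1 + ratio),
           tsk = row$TSK)
    })
  })
}
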