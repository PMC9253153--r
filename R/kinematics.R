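#' Construct an angle waveform
#'
#' A uniformly sampled joint-angle time series for one movement plane.
#'
#' @param samples Numeric vector of angles in degrees (>= 2 finite values).
#' @param fs_hz Sampling rate in Hz.
#' @param plane Movement-plane label.
#' @return A `necknet_waveform` list with `samples`, `fs_hz`, `plane`.
#' @export
angle_waveform <- function(samples, fs_hz = 100, plane = "flexion-extension") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a waveform needs at least 2 samples")
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  structure(list(samples = samples, fs_hz = fs_hz, plane = plane),
            class = "necknet_waveform")
}

#' @export
print.necknet_waveform <- function(x, ...) {
  cat("Angle waveform (", x$plane, "): ", length(x$samples), " samples @ ",
      x$fs_hz, " Hz, ", round(length(x$samples) / x$fs_hz, 2), " s\n",
      sep = "")
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase,
#' DC gain 1) with odd-reflection padding at both ends so start-up
#' transients do not contaminate the output. Defaults follow the standard
#' cervical-kinematics processing: 10th order per pass, 10 Hz cutoff.
#'
#' @param w A `necknet_waveform`.
#' @param order Filter order per pass (default 10).
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist rate.
#' @return Filtered `necknet_waveform` of identical length.
#' @export
lowpass_filter <- function(w, order = 10, cutoff_hz = 10) {
  stopifnot(inherits(w, "necknet_waveform"))
  if (cutoff_hz >= w$fs_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency ", w$fs_hz / 2)
  n <- length(w$samples)
  minlen <- 3 * order + 1
  if (n <= minlen)
    stop("waveform too short to filter: need more than ", minlen,
         " samples, got ", n)
  bf <- signal::butter(order, cutoff_hz / (w$fs_hz / 2))
  pad <- min(n - 1, max(3 * order, round(2 * w$fs_hz)))
  x <- w$samples
  ext <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
           2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, ext)
  angle_waveform(y[(pad + 1):(pad + n)], fs_hz = w$fs_hz, plane = w$plane)
}

#' Numerical differentiation of an angle waveform
#'
#' Central differences in the interior, one-sided differences at the ends;
#' the output has the same length and sampling rate as the input.
#'
#' @param w A `necknet_waveform` with at least 3 samples.
#' @return A `necknet_velocity` list with `samples` (deg/s), `fs_hz`,
#'   `plane`.
#' @export
differentiate <- function(w) {
  stopifnot(inherits(w, "necknet_waveform"))
  x <- w$samples
  n <- length(x)
  if (n < 3) stop("differentiation needs at least 3 samples")
  v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * w$fs_hz
  structure(list(samples = v, fs_hz = w$fs_hz, plane = w$plane),
            class = "necknet_velocity")
}

#' Detect movement cycles and directional half-cycle segments
#'
#' Locates the angle extrema (zero crossings of the angular velocity with a
#' minimum prominence relative to the largest excursion) on a filtered
#' waveform. Movements are the extremum-to-extremum transitions, labelled
#' by their direction; the number of detected cycles is the count of
#' positive-direction peaks.
#'
#' @param w A filtered `necknet_waveform`.
#' @param min_prominence Extrema must exceed this fraction of the maximal
#'   absolute excursion (default 0.3).
#' @return List with `n_cycles`, `peak_samples` (positive peaks),
#'   `segments` (data frame: `cycle_index`, `start_sample`, `end_sample`,
#'   `direction`). A waveform with no detectable peaks yields zero cycles,
#'   an empty segment table, and a warning.
#' @export
detect_cycles <- function(w, min_prominence = 0.3) {
  stopifnot(inherits(w, "necknet_waveform"))
  th <- w$samples
  n <- length(th)
  v <- differentiate(w)$samples
  amp <- max(abs(th))
  cand <- which(diff(sign(v[-n])) != 0)
  cand <- cand[abs(th[cand]) > min_prominence * amp]
  if (length(cand) == 0) {
    warning("no movement peaks detected")
    return(list(n_cycles = 0L, peak_samples = integer(0),
                segments = data.frame(cycle_index = integer(0),
                                      start_sample = integer(0),
                                      end_sample = integer(0),
                                      direction = character(0))))
  }
  # refine each candidate to the local extremum of the angle and merge
  # candidates that collapse onto the same extremum
  half <- max(5L, round(0.2 * w$fs_hz))
  ext <- vapply(cand, function(i) {
    win <- max(1, i - half):min(n, i + half)
    win[which.max(abs(th[win]))]
  }, integer(1))
  ext <- sort(unique(ext))
  # enforce alternation: keep the larger of consecutive same-sign extrema
  keep <- rep(TRUE, length(ext))
  if (length(ext) > 1) {
    for (k in 2:length(ext)) {
      prev <- max(which(keep[1:(k - 1)]))
      if (sign(th[ext[k]]) == sign(th[ext[prev]])) {
        if (abs(th[ext[k]]) > abs(th[ext[prev]])) keep[prev] <- FALSE
        else keep[k] <- FALSE
      }
    }
  }
  ext <- ext[keep]
  peaks <- ext[th[ext] > 0]
  segs <- NULL
  if (length(ext) > 1) {
    segs <- data.frame(
      cycle_index = seq_len(length(ext) - 1),
      start_sample = ext[-length(ext)],
      end_sample = ext[-1],
      direction = ifelse(th[ext[-1]] > th[ext[-length(ext)]], "up", "down"),
      stringsAsFactors = FALSE)
  } else {
    segs <- data.frame(cycle_index = integer(0), start_sample = integer(0),
                       end_sample = integer(0), direction = character(0))
  }
  list(n_cycles = length(peaks), peak_samples = peaks, segments = segs)
}

#' Trim a movement segment at 5 % of its peak speed
#'
#' Within the given segment, movement start is the first sample whose
#' absolute velocity rises above `threshold` times the segment's peak
#' absolute velocity, and movement end is the last sample still above that
#' threshold.
#'
#' @param v A `necknet_velocity`.
#' @param segment List or one-row data frame with `start_sample` and
#'   `end_sample`.
#' @param threshold Fraction of peak speed (default 0.05).
#' @return List with `start_sample`, `end_sample`, `peak_velocity`.
#' @export
segment_movement <- function(v, segment, threshold = 0.05) {
  stopifnot(inherits(v, "necknet_velocity"))
  i0 <- segment$start_sample; i1 <- segment$end_sample
  if (i0 < 1 || i1 > length(v$samples) || i0 >= i1)
    stop("segment out of range")
  sp <- abs(v$samples[i0:i1])
  pk <- max(sp)
  if (pk == 0) stop("segment has all-zero velocity")
  above <- which(sp >= threshold * pk)
  list(start_sample = as.integer(i0 + min(above) - 1),
       end_sample = as.integer(i0 + max(above) - 1),
       peak_velocity = pk)
}

#' Range of motion within a cycle
#'
#' Maximum absolute angular excursion from the neutral (zero) reference
#' within the segment.
#'
#' @param w A `necknet_waveform` (already zeroed to neutral).
#' @param segment List with `start_sample`, `end_sample`.
#' @return Degrees.
#' @export
compute_rom <- function(w, segment) {
  stopifnot(inherits(w, "necknet_waveform"))
  max(abs(w$samples[segment$start_sample:segment$end_sample]))
}

#' Mean absolute angular velocity over a movement segment
#'
#' @param v A `necknet_velocity`.
#' @param segment List with `start_sample`, `end_sample` (typically from
#'   [segment_movement()]).
#' @return Degrees per second.
#' @export
mean_velocity <- function(v, segment) {
  stopifnot(inherits(v, "necknet_velocity"))
  mean(abs(v$samples[segment$start_sample:segment$end_sample]))
}

#' SPARC parameters
#'
#' @param max_cutoff_hz Upper bound of the adaptive spectral cutoff
#'   (default 20 Hz).
#' @param amplitude_threshold Normalized-magnitude threshold that sets the
#'   adaptive cutoff (default 0.05).
#' @param zero_padding_factor FFT zero-padding exponent: the transform
#'   length is the next power of two times `2^zero_padding_factor`
#'   (default 4).
#' @return A `necknet_sparc_params` list.
#' @export
sparc_params <- function(max_cutoff_hz = 20, amplitude_threshold = 0.05,
                         zero_padding_factor = 4) {
  stopifnot(max_cutoff_hz > 0, amplitude_threshold > 0,
            amplitude_threshold < 1, zero_padding_factor >= 1)
  structure(list(max_cutoff_hz = max_cutoff_hz,
                 amplitude_threshold = amplitude_threshold,
                 zero_padding_factor = as.integer(zero_padding_factor)),
            class = "necknet_sparc_params")
}

#' Spectral arc length (SPARC) movement-smoothness metric
#'
#' Computes the arc length of the normalized magnitude spectrum of the
#' speed profile: with `V(f)` the zero-padded DFT magnitude of the
#' segment's absolute velocity and `Vhat = V / V(0)`, the adaptive cutoff
#' is `f_c = min(max_cutoff_hz, highest f with Vhat >= threshold)` and
#' `SPARC = -integral_0^f_c sqrt((1/f_c)^2 + (dVhat/df)^2) df`. Values are
#' strictly negative; smoother (lower-bandwidth) speed profiles give
#' values closer to zero, and the metric is invariant to amplitude
#' scaling of the speed profile.
#'
#' @param v A `necknet_velocity`.
#' @param segment List with `start_sample`, `end_sample`; at least 8
#'   samples.
#' @param params A [sparc_params()].
#' @return Negative scalar.
#' @export
sparc <- function(v, segment, params = sparc_params()) {
  stopifnot(inherits(v, "necknet_velocity"))
  sp <- abs(v$samples[segment$start_sample:segment$end_sample])
  if (length(sp) < 8) stop("SPARC needs a segment of at least 8 samples")
  if (max(sp) == 0) stop("zero speed within segment: V(0) = 0")
  fs <- v$fs_hz
  nfft <- 2^(ceiling(log2(length(sp))) + params$zero_padding_factor)
  f <- (seq_len(nfft) - 1) * fs / nfft
  Mf <- Mod(fft(c(sp, rep(0, nfft - length(sp)))))
  Mf <- Mf / Mf[1]   # V(0) = sum of the nonnegative speed > 0
  sel <- f <= params$max_cutoff_hz
  f_sel <- f[sel]; M_sel <- Mf[sel]
  last <- max(which(M_sel >= params$amplitude_threshold))
  fc <- f_sel[last]
  keep <- seq_len(last)
  -sum(sqrt(diff(f_sel[keep] / fc)^2 + diff(M_sel[keep])^2))
}

#' Extract per-movement kinematic features from one recording
#'
#' Full single-waveform pipeline: re-zero to the neutral reference (median
#' angle over the first 0.5 s), zero-phase low-pass filter, differentiate,
#' detect cycles, trim each extremum-to-extremum movement at 5 % of its
#' peak speed, and compute ROM, mean velocity, and SPARC per movement.
#' Movements whose segmentation fails are dropped with a warning.
#'
#' @param w A raw `necknet_waveform`.
#' @param filter_order,filter_cutoff_hz Butterworth settings per pass.
#' @param threshold Speed-onset threshold as a fraction of peak speed.
#' @param params A [sparc_params()].
#' @param min_prominence Passed to [detect_cycles()].
#' @return List with `n_cycles` and `movements`, a data frame of `plane`,
#'   `direction`, `cycle`, `rom_deg`, `mean_velocity_deg_s`, `sparc`.
#' @export
#' @examples
#' w <- generate_angle_waveform(movement_profile(seed = 3))
#' head(extract_waveform_features(w)$movements)
extract_waveform_features <- function(w, filter_order = 10,
                                      filter_cutoff_hz = 10,
                                      threshold = 0.05,
                                      params = sparc_params(),
                                      min_prominence = 0.3) {
  stopifnot(inherits(w, "necknet_waveform"))
  neutral <- median(w$samples[seq_len(min(length(w$samples),
                                          max(2, round(0.5 * w$fs_hz))))])
  w0 <- angle_waveform(w$samples - neutral, w$fs_hz, w$plane)
  wf <- lowpass_filter(w0, order = filter_order, cutoff_hz = filter_cutoff_hz)
  v <- differentiate(wf)
  cyc <- detect_cycles(wf, min_prominence = min_prominence)
  segs <- cyc$segments
  rows <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    res <- tryCatch({
      seg <- segment_movement(v, segs[k, ], threshold = threshold)
      data.frame(
        plane = w$plane,
        direction = direction_label(w$plane, segs$direction[k]),
        cycle = segs$cycle_index[k],
        rom_deg = compute_rom(wf, segs[k, ]),
        mean_velocity_deg_s = mean_velocity(v, seg),
        sparc = sparc(v, seg, params),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("movement ", k, " dropped: ", conditionMessage(e))
      NULL
    })
    rows[[k]] <- res
  }
  list(n_cycles = cyc$n_cycles, movements = do.call(rbind, rows))
}

# Map the geometric direction of a half-cycle to its anatomical label.
direction_label <- function(plane, dir) {
  switch(plane,
         "flexion-extension" = ifelse(dir == "up", "flexion", "extension"),
         "rotation" = ifelse(dir == "up", "rotation_right", "rotation_left"),
         "lateral-flexion" = ifelse(dir == "up", "lateral_right",
                                    "lateral_left"),
         dir)
}
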