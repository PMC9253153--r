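test_that("zero-phase filtering has unit DC gain and the analytic band edges", {
  w <- angle_waveform(rep(30, 500))
  expect_lt(max(abs(lowpass_filter(w)$samples - 30)), 1e-6)

  # analytic per-pass Butterworth magnitude (order 10, cutoff 10 Hz),
  # squared for the forward-backward application
  t <- seq(0, 10, by = 1 / 100)
  gain <- function(f) (1 / (1 + (f / 10)^20))  # |H|^2 = two passes
  w1 <- angle_waveform(sin(2 * pi * 1 * t))
  y1 <- lowpass_filter(w1)$samples
  expect_equal(max(abs(y1[200:800])), gain(1), tolerance = 0.01)

  w25 <- angle_waveform(sin(2 * pi * 25 * t))
  y25 <- lowpass_filter(w25)$samples
  expect_lt(max(abs(y25[200:800])), 0.01)
  expect_lt(gain(25), 0.01)  # the analytic response agrees it must vanish

  expect_error(lowpass_filter(angle_waveform(rnorm(10))), "too short")
  expect_error(lowpass_filter(angle_waveform(rnorm(100), fs_hz = 15)),
               "Nyquist")
})

test_that("differentiation is exact on polynomials and O(dt^2) on sinusoids", {
  expect_equal(differentiate(angle_waveform(rep(5, 50)))$samples, rep(0, 50))

  t <- seq(0, 2, by = 0.01)
  ramp <- differentiate(angle_waveform(10 * t))$samples
  expect_equal(ramp, rep(10, length(t)), tolerance = 1e-10)

  A <- 3; f <- 2
  v <- differentiate(angle_waveform(A * sin(2 * pi * f * t)))$samples
  truth <- 2 * pi * f * A * cos(2 * pi * f * t)
  interior <- 2:(length(t) - 1)
  # central-difference error bound: |v - v_true| <= max|theta'''| dt^2 / 6
  bound <- A * (2 * pi * f)^3 * 0.01^2 / 6
  expect_lt(max(abs(v[interior] - truth[interior])), bound * 1.01)

  expect_error(differentiate(angle_waveform(c(1, 2))), "at least 3")
})

test_that("cycle detection counts cycles and locates peaks", {
  w <- generate_angle_waveform(movement_profile(n_cycles = 10,
    jerk_noise_amplitude = 0, cycle_cv = 0))
  cyc <- detect_cycles(w)
  expect_identical(cyc$n_cycles, 10L)

  ramp <- angle_waveform(seq(0, 50, length.out = 500))
  expect_warning(res <- detect_cycles(ramp), "no movement peaks")
  expect_identical(res$n_cycles, 0L)
  expect_identical(nrow(res$segments), 0L)

  # 3-cycle waveform with known peak positions (oracle: argmax per cycle)
  prof <- movement_profile(n_cycles = 3, rom_deg = 40,
                           mean_velocity_deg_s = 50,
                           jerk_noise_amplitude = 0, cycle_cv = 0)
  w3 <- generate_angle_waveform(prof)
  cyc3 <- detect_cycles(w3)
  truth <- which(w3$samples == max(w3$samples))
  per_cycle_peaks <- vapply(cyc3$peak_samples, function(i)
    min(abs(i - which(abs(w3$samples - 40) < 1e-6))), numeric(1))
  expect_identical(cyc3$n_cycles, 3L)
  expect_true(all(per_cycle_peaks <= 2))
})

test_that("5 percent segmentation matches the closed-form ramp crossing", {
  # linear ramp to 100 deg/s over 1 s at fs 100: threshold 5 crossed exactly
  # 5 samples after motion onset
  v <- structure(list(samples = c(rep(0, 20), seq(0, 100, by = 1),
                                  rep(100, 30), rep(0, 20)),
                      fs_hz = 100, plane = "flexion-extension"),
                 class = "necknet_velocity")
  seg <- segment_movement(v, list(start_sample = 1,
                                  end_sample = length(v$samples)))
  expect_identical(seg$start_sample, 20L + 5L + 1L)  # v = 5 at onset + 5

  # rectangular pulse: the segment is the full pulse
  vp <- structure(list(samples = c(rep(0, 10), rep(80, 40), rep(0, 10)),
                       fs_hz = 100, plane = "x"), class = "necknet_velocity")
  segp <- segment_movement(vp, list(start_sample = 1, end_sample = 60))
  expect_identical(c(segp$start_sample, segp$end_sample), c(11L, 50L))

  # idempotence: re-segmenting an already trimmed segment changes nothing
  seg2 <- segment_movement(v, seg)
  expect_identical(seg[1:2], seg2[1:2])

  expect_equal(0.05 * 61.6, 3.08)
  expect_error(segment_movement(vp, list(start_sample = 1, end_sample = 5)),
               "all-zero")
})

test_that("ROM and mean velocity extract the constructed values", {
  th <- 50 * sin(pi * seq(0, 1, by = 0.01))
  w <- angle_waveform(th)
  expect_equal(compute_rom(w, list(start_sample = 1, end_sample = 101)), 50)

  set.seed(1)
  noisy <- angle_waveform(th + runif(101, -0.5, 0.5))
  expect_lt(abs(compute_rom(noisy, list(start_sample = 1,
                                        end_sample = 101)) - 50), 0.5)

  v <- structure(list(samples = rep(60, 80), fs_hz = 100, plane = "x"),
                 class = "necknet_velocity")
  expect_equal(mean_velocity(v, list(start_sample = 1, end_sample = 80)), 60)

  # triangular speed profile, peak P: sample-mean oracle
  tri <- structure(list(samples = c(seq(0, 100, 2), seq(98, 0, -2)),
                        fs_hz = 100, plane = "x"),
                   class = "necknet_velocity")
  seg <- segment_movement(tri, list(start_sample = 1,
                                    end_sample = length(tri$samples)))
  oracle <- mean(abs(tri$samples[seg$start_sample:seg$end_sample]))
  expect_equal(mean_velocity(tri, seg), oracle)
  # P/2 plus the 5 % threshold correction: mean of a trimmed ramp is
  # (threshold * P + P) / 2
  expect_equal(mean_velocity(tri, seg), 100 * (1 + 0.05) / 2,
               tolerance = 0.02)
})

test_that("SPARC is scale-invariant, matches the analytic-spectrum oracle, and ranks contamination", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  bump <- exp(-(t - 1)^2 / (2 * 0.1^2))
  vel <- function(x) structure(list(samples = x, fs_hz = fs, plane = "x"),
                               class = "necknet_velocity")
  seg <- list(start_sample = 1, end_sample = length(t))

  s1 <- sparc(vel(bump), seg)
  s2 <- sparc(vel(2 * bump), seg)
  expect_identical(s1, s2)
  expect_lt(s1, 0)

  # dense-quadrature oracle on the analytic spectrum of a Gaussian bump:
  # |V(f)| / V(0) = exp(-2 pi^2 sigma^2 f^2)
  sig <- 0.1
  vhat <- function(f) exp(-2 * pi^2 * sig^2 * f^2)
  fgrid <- seq(0, 20, by = 1e-4)
  m <- vhat(fgrid)
  fc <- fgrid[max(which(m >= 0.05))]
  keep <- fgrid <= fc
  oracle <- -sum(sqrt(diff(fgrid[keep] / fc)^2 + diff(m[keep])^2))
  expect_equal(s1, oracle, tolerance = 0.01)

  # strictly decreasing under growing 10 Hz contamination
  vals <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(a)
    sparc(vel(bump + a * sin(2 * pi * 10 * t) * (t > 0.5 & t < 1.5)), seg),
    numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(sparc(vel(rep(0, 100)),
                     list(start_sample = 1, end_sample = 100)),
               "zero speed")
  expect_error(sparc(vel(bump), list(start_sample = 1, end_sample = 5)),
               "at least 8")
})

test_that("ROM, mean velocity, and SPARC are invariant to time reversal", {
  w <- generate_angle_waveform(movement_profile(seed = 8))
  wf <- lowpass_filter(w)
  v <- differentiate(wf)
  segs <- detect_cycles(wf)$segments
  seg <- segment_movement(v, segs[3, ])
  n <- length(v$samples)

  wr <- angle_waveform(rev(wf$samples), wf$fs_hz, wf$plane)
  vr <- structure(list(samples = rev(-v$samples), fs_hz = v$fs_hz,
                       plane = v$plane), class = "necknet_velocity")
  flip <- function(s) list(start_sample = n - s$end_sample + 1,
                           end_sample = n - s$start_sample + 1)
  expect_equal(compute_rom(wf, segs[3, ]),
               compute_rom(wr, flip(segs[3, ])))
  expect_equal(mean_velocity(v, seg), mean_velocity(vr, flip(seg)))
  expect_equal(sparc(v, seg), sparc(vr, flip(seg)), tolerance = 1e-10)
})

test_that("the extraction pipeline recovers noise-free profiles within tolerance", {
  prof <- movement_profile(rom_deg = 45, mean_velocity_deg_s = 70,
                           jerk_noise_amplitude = 0, cycle_cv = 0)
  ex <- extract_waveform_features(generate_angle_waveform(prof))
  expect_equal(ex$n_cycles, 10L)
  expect_lt(abs(mean(ex$movements$rom_deg) - 45) / 45, 0.02)
  expect_lt(abs(mean(ex$movements$mean_velocity_deg_s) - 70) / 70, 0.05)
  expect_true(all(ex$movements$sparc < 0))
  expect_setequal(unique(ex$movements$direction), c("flexion", "extension"))
})
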