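test_that("identical configurations reproduce bitwise-identical dyads", {
  cfg <- sim_config(duration = 90, seed = 11)
  d1 <- generate_dyad(cfg)
  d2 <- generate_dyad(cfg)
  expect_identical(d1$teacher, d2$teacher)
  expect_identical(d1$student, d2$student)
  expect_identical(generate_latent_signal(cfg), generate_latent_signal(cfg))
  d3 <- generate_dyad(sim_config(duration = 90, seed = 12))
  expect_false(identical(d1$teacher, d3$teacher))
})

test_that("teacher stream is unaffected by student-side settings", {
  base <- sim_config(duration = 90, seed = 5)
  G <- diag(1, 18)
  coupled <- sim_config(duration = 90, seed = 5, coupling_gain = G)
  no_hbr <- sim_config(duration = 90, seed = 5, generate_hbr = FALSE)
  expect_identical(generate_dyad(base)$teacher, generate_dyad(coupled)$teacher)
  expect_identical(generate_dyad(base)$teacher, generate_dyad(no_hbr)$teacher)
  expect_identical(generate_dyad(base)$student, generate_dyad(no_hbr)$student)
})

test_that("latent signal handles empty, short and controlled event trains", {
  cfg0 <- sim_config(duration = 90, n_latent_events = 0L, seed = 1)
  expect_identical(generate_latent_signal(cfg0), numeric(round(90 * 7.81)))
  expect_error(generate_latent_signal(sim_config(duration = 5, seed = 1)),
               "too short")
  # single event at t = 0 without band-limiting: peak lands at the
  # configured time-to-peak, matching the closed form on the sample grid
  cfg1 <- sim_config(duration = 60, n_latent_events = 1L,
                     band_limit = FALSE, seed = 1)
  y <- generate_latent_signal(cfg1, onsets = 1L)
  fs <- cfg1$sampling_rate
  expect_lt(abs((which.max(y) - 1) / fs - cfg1$hrf_peak), 1 / fs + 1e-12)
  ref <- double_gamma_grid(fs, cfg1$hrf_peak, cfg1$hrf_undershoot_peak,
                           cfg1$hrf_undershoot_ratio, cfg1$hrf_dispersion,
                           span = 2 * cfg1$hrf_undershoot_peak)
  expect_equal(which.max(y), which.max(ref))
  expect_equal(max(y), max(ref), tolerance = 1e-10)
})

test_that("latent signal power is concentrated in the 0.01-0.2 Hz band", {
  cfg <- sim_config(duration = 900, seed = 21)
  y <- generate_latent_signal(cfg)
  n <- length(y)
  fs <- cfg$sampling_rate
  sp <- Mod(fft(y - mean(y)))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & f >= 0.01 & f <= 0.2
  frac_out <- 1 - sum(sp[inband]) / sum(sp[half])
  expect_lt(frac_out, 0.05)
})

test_that("all-zero gain yields independent subjects and empty ground truth", {
  cfg <- sim_config(duration = 900, seed = 31, noise = ar1_noise_spec(0.9),
                    n_latent_events = 0L)
  d <- generate_dyad(cfg)
  expect_equal(nrow(d$ground_truth$coupled_channel_pairs), 0)
  rhos <- vapply(1:18, function(j)
    abs(spearman_rho(d$teacher[, j], d$student[, j])), numeric(1))
  expect_lt(mean(rhos), 0.1)
})

test_that("identity gain with zero noise copies the teacher signal part", {
  silent <- noise_spec(cardiac = c(1.2, 0), respiratory = c(0.3, 0),
                       mayer = c(0.1, 0), vasomotion = c(0.04, 0),
                       drift_amplitude = 0, white_sd = 0)
  cfg <- sim_config(duration = 90, coupling_gain = diag(1, 18),
                    noise = silent, student_snr = Inf, teacher_snr = Inf,
                    seed = 3)
  d <- generate_dyad(cfg)
  expect_equal(d$student, d$ground_truth$teacher_signal, tolerance = 1e-12)
  expect_equal(d$teacher, d$ground_truth$teacher_signal, tolerance = 1e-12)
})

test_that("unit gain at SNR 1 gives signal-student correlation near 1/sqrt(2)", {
  cfg <- coupled_config(channels = 5, gain = 1, duration = 900, seed = 41)
  d <- generate_dyad(cfg)
  expect_equal(unname(d$ground_truth$snr[5]), 1, tolerance = 1e-9)
  r <- cor(d$ground_truth$teacher_signal[, 5], d$student[, 5])
  expect_equal(r, 1 / sqrt(2), tolerance = 0.05)
  pairs <- d$ground_truth$coupled_channel_pairs
  expect_equal(unname(pairs[1, ]), c(5L, 5L), ignore_attr = TRUE)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(duration = -1), "duration")
  expect_error(sim_config(sampling_rate = 0), "sampling_rate")
  G <- matrix(0, 18, 18); G[1, 1] <- NaN
  expect_error(sim_config(coupling_gain = G), "finite")
  expect_error(sim_config(coupling_gain = matrix(0, 3, 3)), "n_channels")
})

test_that("rendered intensities invert through the Beer-Lambert decode", {
  cfg <- sim_config(duration = 90, seed = 13)
  d <- generate_dyad(cfg)
  raw <- render_raw_intensities(d)
  for (who in c("teacher", "student")) {
    dec <- mbll(raw[[who]])
    centred <- scale(d[[who]], scale = FALSE)
    scale_of <- max(abs(centred))
    expect_lt(max(abs(dec$values - centred)) / scale_of, 1e-9)
  }
})

test_that("zero concentration change renders constant baseline intensities", {
  z <- dyad_recording(matrix(0, 50, 18), matrix(0, 50, 18), 7.81)
  raw <- render_raw_intensities(z)
  expect_true(all(raw$teacher$intensities == 1))
  expect_true(all(raw$student$intensities == 1))
})

test_that("doubling concentrations doubles optical-density excursions", {
  cfg <- sim_config(duration = 60, seed = 17, generate_hbr = FALSE)
  d <- generate_dyad(cfg)
  d2 <- d
  d2$teacher <- 2 * d$teacher
  d2$student <- 2 * d$student
  od <- function(r) -log10(r$teacher$intensities[, , 1])
  o1 <- od(render_raw_intensities(d))
  o2 <- od(render_raw_intensities(d2))
  expect_equal(sweep(o2, 2, colMeans(o2)), 2 * sweep(o1, 2, colMeans(o1)),
               tolerance = 1e-9)
})

test_that("extreme concentrations that break the optical model are errors", {
  big <- dyad_recording(matrix(c(-5e4, 5e4), 50, 18), matrix(0, 50, 18), 7.81)
  expect_error(render_raw_intensities(big), "non-positive|non-finite")
})
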