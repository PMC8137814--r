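#' Physiological noise specification
#'
#' Amplitudes and centre frequencies of the noise components added to every
#' simulated channel. Oscillatory components (cardiac, respiratory, Mayer
#' waves, slow vasomotion) are generated as narrowband AR(2) processes
#' rather than pure sinusoids so that no two channels share a deterministic
#' waveform; `drift` is a near-unit-root AR(1) and `white_sd` plain Gaussian
#' noise. Amplitudes are standard deviations on the same (micromolar) scale
#' as the unit-variance latent haemodynamic signal.
#'
#' @param cardiac,respiratory,mayer,vasomotion Length-2 numeric vectors
#'   `c(freq_hz, amplitude)`.
#' @param drift_amplitude Amplitude of the slow AR(1) drift component.
#' @param drift_ar AR(1) coefficient of the drift (close to 1).
#' @param white_sd Standard deviation of the white noise floor.
#' @param bandwidth_rho Pole radius of the AR(2) narrowband components in
#'   (0, 1); larger means narrower band.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cardiac = c(1.2, 0.35), respiratory = c(0.3, 0.3),
                       mayer = c(0.1, 0.45), vasomotion = c(0.04, 0.6),
                       drift_amplitude = 0.5, drift_ar = 0.998,
                       white_sd = 0.35, bandwidth_rho = 0.97) {
  structure(list(cardiac = cardiac, respiratory = respiratory,
                 mayer = mayer, vasomotion = vasomotion,
                 drift_amplitude = drift_amplitude, drift_ar = drift_ar,
                 white_sd = white_sd, bandwidth_rho = bandwidth_rho),
            class = "noise_spec")
}

#' Simulation configuration for synthetic dyads
#'
#' Defines one simulated teacher-student recording: ~15 minutes at 7.81 Hz
#' (about 7,000 samples) and 18 channels per subject by default, with a
#' latent event-related haemodynamic signal shared across the teacher's
#' channels and a linear, instantaneous teacher-to-student coupling encoded
#' by an `n_channels x n_channels` gain matrix. An all-zero gain matrix
#' defines a null dyad. Identical configurations (including `seed`) always
#' reproduce bitwise-identical data.
#'
#' @param n_channels Channels per subject (default 18).
#' @param sampling_rate Hz (default 7.81).
#' @param duration Recording length in seconds (default 900).
#' @param coupling_gain `n_channels x n_channels` matrix; entry `[i, j]` is
#'   the linear influence of teacher channel `i`'s noise-free signal part
#'   on student channel `j`. Default all zero (null dyad).
#' @param coupling_lag Integer sample lag applied to the coupled signal
#'   part (default 0: instantaneous coupling, matching the linear model
#'   class fitted downstream; nonzero values are for robustness studies).
#' @param n_latent_events Number of haemodynamic events in the latent
#'   signal (default 60, roughly one per 15 s of task).
#' @param hrf_peak,hrf_undershoot_peak,hrf_undershoot_ratio,hrf_dispersion
#'   Double-gamma haemodynamic response parameters: time-to-peak (s),
#'   undershoot peak time (s), undershoot amplitude ratio, dispersion (s).
#' @param noise A [noise_spec()].
#' @param student_snr Signal-to-noise variance ratio enforced on student
#'   channels that carry a coupled signal part (default 1). `Inf` disables
#'   student noise scaling checks and leaves zero-amplitude noise alone.
#' @param teacher_snr Same, for teacher channels (default 1).
#' @param band_limit If `TRUE` (default) the latent signal is band-limited
#'   to 0.01-0.2 Hz after HRF convolution, so that coupling survives the
#'   preprocessing band-pass.
#' @param generate_hbr If `TRUE` (default) also simulate deoxyhemoglobin as
#'   -1/3 the HbO2 series plus noise, used only by the two-wavelength
#'   forward model in [render_raw_intensities()].
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(duration = 120, seed = 7)
#' d <- generate_dyad(cfg)
#' d
sim_config <- function(n_channels = 18L, sampling_rate = 7.81, duration = 900,
                       coupling_gain = matrix(0, n_channels, n_channels),
                       coupling_lag = 0L, n_latent_events = 60L,
                       hrf_peak = 6, hrf_undershoot_peak = 16,
                       hrf_undershoot_ratio = 1 / 6, hrf_dispersion = 1,
                       noise = noise_spec(), student_snr = 1,
                       teacher_snr = 1, band_limit = TRUE,
                       generate_hbr = TRUE, seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  coupling_gain <- as.matrix(coupling_gain)
  if (!all(dim(coupling_gain) == c(n_channels, n_channels)))
    stop("coupling_gain must be n_channels x n_channels")
  if (!all(is.finite(coupling_gain)))
    stop("coupling_gain entries must be finite")
  if (coupling_lag < 0) stop("coupling_lag must be >= 0")
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, duration = duration,
                 coupling_gain = coupling_gain,
                 coupling_lag = as.integer(coupling_lag),
                 n_latent_events = as.integer(n_latent_events),
                 hrf_peak = hrf_peak,
                 hrf_undershoot_peak = hrf_undershoot_peak,
                 hrf_undershoot_ratio = hrf_undershoot_ratio,
                 hrf_dispersion = hrf_dispersion,
                 noise = noise, student_snr = student_snr,
                 teacher_snr = teacher_snr, band_limit = band_limit,
                 generate_hbr = generate_hbr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sub-seeds for the independent random streams (latent / teacher noise /
# student noise / HbR noise); kept below 2^31 for set.seed()
stream_seed <- function(seed, k) as.integer((abs(seed) %% 2000000000L) + k)

#' Double-gamma haemodynamic response kernel
#'
#' Canonical double-gamma HRF sampled on the recording grid:
#' `g(t; p) = (t/p)^(p/d) * exp(-(t - p)/d)`, peaking exactly at `t = p`,
#' minus `ratio` times the same form peaking at the undershoot time.
#'
#' @param sampling_rate Hz.
#' @param peak,undershoot_peak Times to peak/undershoot (s).
#' @param undershoot_ratio Undershoot amplitude ratio.
#' @param dispersion Width parameter (s).
#' @param span Kernel support in seconds (default twice the undershoot
#'   peak).
#' @return Numeric vector of kernel values starting at t = 0.
#' @export
hrf_kernel <- function(sampling_rate, peak = 6, undershoot_peak = 16,
                       undershoot_ratio = 1 / 6, dispersion = 1,
                       span = 2 * undershoot_peak) {
  t <- seq(0, span, by = 1 / sampling_rate)
  g <- function(tt, p, d) {
    out <- numeric(length(tt))
    pos <- tt > 0
    out[pos] <- exp((p / d) * log(tt[pos] / p) - (tt[pos] - p) / d)
    out
  }
  g(t, peak, dispersion) - undershoot_ratio * g(t, undershoot_peak, dispersion)
}

#' Latent task-related haemodynamic signal
#'
#' A train of randomly placed events convolved with the double-gamma HRF,
#' standing in for shared task-evoked activity during a continuous
#' interaction task. With `band_limit = TRUE` in the configuration the
#' result is additionally zero-phase band-passed to 0.01-0.2 Hz, so nearly
#' all of its spectral mass lies inside the band the preprocessing filter
#' retains.
#'
#' @param config A [sim_config()].
#' @param onsets Optional integer sample indices of event onsets,
#'   overriding random placement (used for controlled tests).
#' @return Numeric vector of length `round(duration * sampling_rate)`.
#' @export
generate_latent_signal <- function(config, onsets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$duration * config$sampling_rate)
  min_dur <- 2 * config$hrf_peak
  if (config$n_latent_events > 0L && config$duration < min_dur)
    stop(sprintf("duration %.1f s too short to place events; need at least %.1f s",
                 config$duration, min_dur))
  if (config$n_latent_events == 0L && is.null(onsets))
    return(numeric(n))
  ev <- numeric(n)
  if (is.null(onsets)) {
    set.seed(stream_seed(config$seed, 0L))
    onsets <- sample.int(n, config$n_latent_events, replace = TRUE)
  }
  stopifnot(all(onsets >= 1L), all(onsets <= n))
  for (o in onsets) ev[o] <- ev[o] + 1
  h <- hrf_kernel(config$sampling_rate, config$hrf_peak,
                  config$hrf_undershoot_peak, config$hrf_undershoot_ratio,
                  config$hrf_dispersion)
  y <- stats::convolve(ev, rev(h), type = "open")[seq_len(n)]
  if (isTRUE(config$band_limit))
    y <- bandpass_filter(y, config$sampling_rate, 0.01, 0.2)
  y
}

# one narrowband AR(2) series with unit empirical sd
ar2_narrowband <- function(n, freq, sampling_rate, rho) {
  theta <- 2 * pi * freq / sampling_rate
  x <- as.numeric(stats::filter(stats::rnorm(n + 200),
                                c(2 * rho * cos(theta), -rho^2),
                                method = "recursive"))
  x <- x[-seq_len(200)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# time x n_channels physiological noise matrix (draws from current RNG)
noise_matrix <- function(n, n_channels, ns, sampling_rate) {
  out <- matrix(0, n, n_channels)
  for (j in seq_len(n_channels)) {
    x <- numeric(n)
    for (comp in list(ns$cardiac, ns$respiratory, ns$mayer, ns$vasomotion)) {
      if (comp[2] > 0)
        x <- x + comp[2] * ar2_narrowband(n, comp[1], sampling_rate,
                                          ns$bandwidth_rho)
    }
    if (ns$drift_amplitude > 0) {
      d <- as.numeric(stats::filter(stats::rnorm(n + 200), ns$drift_ar,
                                    method = "recursive"))[-seq_len(200)]
      s <- stats::sd(d)
      x <- x + ns$drift_amplitude * (if (s > 0) d / s else d)
    }
    if (ns$white_sd > 0) x <- x + stats::rnorm(n, sd = ns$white_sd)
    out[, j] <- x
  }
  out
}

# scale noise columns so var(signal)/var(noise) = snr on channels where the
# signal part is non-degenerate; channels without signal are left alone
apply_snr <- function(signal, noise, snr) {
  if (!is.finite(snr)) return(noise)
  if (snr <= 0) stop("snr must be positive")
  for (j in seq_len(ncol(noise))) {
    ssd <- stats::sd(signal[, j])
    nsd <- stats::sd(noise[, j])
    if (ssd > 0 && nsd > 0)
      noise[, j] <- noise[, j] * (ssd / (nsd * sqrt(snr)))
  }
  noise
}

#' Simulate one teacher-student dyad with known ground truth
#'
#' The teacher's channels are channel-specific loadings on the latent
#' haemodynamic signal plus independent physiological noise. The student's
#' noise-free signal part is the teacher's noise-free part multiplied by
#' the coupling gain matrix (optionally lagged), plus independent noise
#' drawn from a separate random stream; with an all-zero gain matrix the
#' two subjects are independent by construction. Student-channel noise is
#' scaled to the configured signal-to-noise ratio wherever a coupled
#' signal part exists.
#'
#' @param config A [sim_config()].
#' @param id Dyad identifier.
#' @return A [dyad_recording()] whose `ground_truth` element lists
#'   `coupled_channel_pairs` (teacher, student index pairs with nonzero
#'   gain), the `latent_signal`, per-channel `snr`, and the noise-free
#'   `teacher_signal` / `student_signal` parts.
#' @export
generate_dyad <- function(config, id = "dyad") {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$duration * config$sampling_rate)
  nch <- config$n_channels
  G <- config$coupling_gain

  latent <- generate_latent_signal(config)
  ls <- stats::sd(latent)
  if (ls > 0) latent <- latent / ls

  set.seed(stream_seed(config$seed, 0L))
  # burn the event draw so loadings are reproducible yet distinct
  if (config$n_latent_events > 0L) invisible(sample.int(n, config$n_latent_events, replace = TRUE))
  loadings <- stats::runif(nch, 0.5, 1.5)
  t_signal <- latent %*% t(loadings)

  s_signal <- t_signal %*% G
  if (config$coupling_lag > 0L && any(G != 0)) {
    L <- config$coupling_lag
    if (L >= n) stop("coupling_lag must be smaller than the series length")
    s_signal <- rbind(matrix(0, L, nch), s_signal[seq_len(n - L), , drop = FALSE])
  }

  set.seed(stream_seed(config$seed, 1L))
  t_noise <- noise_matrix(n, nch, config$noise, config$sampling_rate)
  t_noise <- apply_snr(t_signal, t_noise, config$teacher_snr)

  set.seed(stream_seed(config$seed, 2L))
  s_noise <- noise_matrix(n, nch, config$noise, config$sampling_rate)
  s_noise <- apply_snr(s_signal, s_noise, config$student_snr)

  teacher <- t_signal + t_noise
  student <- s_signal + s_noise

  hbr <- NULL
  if (isTRUE(config$generate_hbr)) {
    set.seed(stream_seed(config$seed, 3L))
    hbr <- list(teacher = -teacher / 3 + matrix(stats::rnorm(n * nch, sd = 0.05), n, nch),
                student = -student / 3 + matrix(stats::rnorm(n * nch, sd = 0.05), n, nch))
  }

  pairs <- which(G != 0, arr.ind = TRUE)
  colnames(pairs) <- c("teacher_channel", "student_channel")
  snr_ch <- vapply(seq_len(nch), function(j) {
    ssd <- stats::sd(s_signal[, j]); nsd <- stats::sd(s_noise[, j])
    if (nsd > 0) (ssd / nsd)^2 else Inf
  }, numeric(1))

  gt <- list(coupled_channel_pairs = pairs, latent_signal = latent,
             snr = snr_ch, teacher_signal = t_signal,
             student_signal = s_signal, loadings = loadings,
             coupling_gain = G, config = config)
  dyad_recording(teacher, student, config$sampling_rate,
                 default_montage(nch), stage = "hbo2",
                 ground_truth = c(gt, list(hbr = hbr)), id = id)
}

#' Render a dyad as raw two-wavelength optical intensities
#'
#' Inverse of the modified Beer-Lambert conversion: encodes HbO2 (and HbR)
#' concentration changes as light intensities at 760 and 850 nm such that
#' [mbll()] applied with the same extinction coefficients, differential
#' pathlength factors and source-detector distance recovers the
#' (whole-series-mean-centred) input concentrations to numerical precision.
#' Concentration changes are interpreted relative to their whole-series
#' mean, the baseline convention of the decoding step, and are centred
#' before encoding.
#'
#' @param dyad A [dyad_recording()] at the HbO2 stage. If it carries
#'   simulated HbR series in its ground truth these are used; otherwise
#'   HbR is taken as -1/3 of HbO2.
#' @param dpf Differential pathlength factors for (760, 850) nm; defaults
#'   `c(7.25, 6.38)`.
#' @param extinction 2x2 extinction matrix, see [default_extinction()].
#' @param distance Source-detector distance in mm (default 30).
#' @param baseline_intensity Baseline detector intensity (arbitrary units).
#' @return A list of class `raw_dyad` with `raw_recording` elements
#'   `teacher` and `student` (each holding a time x channel x wavelength
#'   intensity array), plus the montage and dyad id.
#' @export
render_raw_intensities <- function(dyad, dpf = c(7.25, 6.38),
                                   extinction = default_extinction(),
                                   distance = 30, baseline_intensity = 1) {
  stopifnot(inherits(dyad, "dyad_recording"), dyad$stage == "hbo2")
  hbr <- dyad$ground_truth$hbr
  enc <- function(hbo2, hbr_m) {
    if (is.null(hbr_m)) hbr_m <- -hbo2 / 3
    hbo2 <- scale(hbo2, scale = FALSE)
    hbr_m <- scale(hbr_m, scale = FALSE)
    n <- nrow(hbo2); nch <- ncol(hbo2)
    path_cm <- (distance / 10) * dpf           # per-wavelength pathlength, cm
    inten <- array(NA_real_, dim = c(n, nch, 2))
    for (w in 1:2) {
      # OD = eps %*% C[mM] * path; concentrations are in uM
      od <- (hbo2 * extinction[w, 1] + hbr_m * extinction[w, 2]) / 1000 * path_cm[w]
      if (any(!is.finite(od)) || any(abs(od) > 4))
        stop("concentration excursions drive intensities non-positive or non-finite")
      inten[, , w] <- baseline_intensity * 10^(-od)
    }
    raw_recording(inten, wavelengths = c(760, 850),
                  sampling_rate = dyad$sampling_rate, montage = dyad$montage)
  }
  structure(list(teacher = enc(dyad$teacher, hbr$teacher),
                 student = enc(dyad$student, hbr$student),
                 montage = dyad$montage, id = dyad$id,
                 ground_truth = dyad$ground_truth),
            class = "raw_dyad")
}

#' @export
print.raw_dyad <- function(x, ...) {
  d <- dim(x$teacher$intensities)
  cat(sprintf("<raw_dyad '%s'> %d samples x %d channels x %d wavelengths per subject\n",
              x$id, d[1], d[2], d[3]))
  invisible(x)
}
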