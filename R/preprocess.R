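#' Raw two-wavelength recording for one subject
#'
#' @param intensities Numeric array, time x channel x wavelength, strictly
#'   non-negative light intensities.
#' @param wavelengths Wavelengths in nm, default `c(760, 850)`.
#' @param sampling_rate Hz.
#' @param montage Channel table, see [default_montage()].
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(intensities, wavelengths = c(760, 850),
                          sampling_rate = 7.81,
                          montage = default_montage(dim(intensities)[2])) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  if (length(wavelengths) < 2) stop("need at least 2 wavelengths")
  if (dim(intensities)[3] != length(wavelengths))
    stop("third array dimension must match number of wavelengths")
  if (dim(intensities)[1] < 2) stop("need at least 2 time samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  validate_montage(montage, dim(intensities)[2])
  structure(list(intensities = intensities, wavelengths = wavelengths,
                 sampling_rate = sampling_rate, montage = montage),
            class = "raw_recording")
}

#' Automated channel quality screening
#'
#' Algorithmic surrogate for visual inspection of raw recordings: flags
#' channels that sit at the detector rail (saturated), contain non-finite
#' samples (missing), or are essentially constant (flat). Flag precedence
#' is missing > saturated > flat > ok; every channel receives exactly one
#' flag.
#'
#' @param raw A [raw_recording()].
#' @param saturation_frac Fraction of samples at the rail that triggers a
#'   `saturated` flag (default 0.05).
#' @param rail_tol Relative tolerance defining "at the rail" (default
#'   0.001 of the rail value).
#' @param missing_frac Fraction of non-finite samples that triggers a
#'   `missing` flag (default 0.05).
#' @param flat_var Variance (relative to the channel's squared mean
#'   intensity) below which a channel is `flat` (default 1e-12).
#' @param rail Detector rail value; defaults to the maximum intensity in
#'   the recording.
#' @return A data.frame of class `qc_report` with one row per channel:
#'   `channel`, `flag`, `frac_rail`, `frac_nonfinite`, `variance`.
#' @export
quality_screen <- function(raw, saturation_frac = 0.05, rail_tol = 0.001,
                           missing_frac = 0.05, flat_var = 1e-12,
                           rail = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  x <- raw$intensities
  if (is.null(rail)) rail <- max(x, na.rm = TRUE)
  nch <- dim(x)[2]
  rep <- data.frame(channel = seq_len(nch), flag = "ok",
                    frac_rail = NA_real_, frac_nonfinite = NA_real_,
                    variance = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(nch)) {
    v <- as.vector(x[, j, ])
    fin <- is.finite(v)
    rep$frac_nonfinite[j] <- mean(!fin)
    rep$frac_rail[j] <- if (any(fin)) mean(abs(v[fin] - rail) <= rail_tol * rail) else 0
    m <- if (any(fin)) mean(v[fin]) else 0
    rep$variance[j] <- if (sum(fin) > 1) stats::var(v[fin]) else 0
    if (rep$frac_nonfinite[j] >= missing_frac) rep$flag[j] <- "missing"
    else if (rep$frac_rail[j] >= saturation_frac) rep$flag[j] <- "saturated"
    else if (rep$variance[j] < flat_var * max(m^2, .Machine$double.eps)) rep$flag[j] <- "flat"
  }
  if (!any(rep$flag == "ok")) stop("no usable channels: all channels flagged by QC")
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, order 3 per pass,
#' applied independently to each column. Defaults retain the haemodynamic
#' band 0.01-0.2 Hz, suppressing slow systemic drift below and cardiac /
#' respiratory cycles above. Zero phase matters here because the analysis
#' regresses one subject's series on another's: phase distortion would
#' shift their temporal alignment.
#'
#' @param x Numeric vector or time x channel matrix.
#' @param sampling_rate Hz.
#' @param low,high Band edges in Hz (defaults 0.01 and 0.2).
#' @param order Butterworth order per pass (default 3).
#' @return Filtered object of the same shape as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, low = 0.01, high = 0.2,
                            order = 3) {
  if (!(low > 0 && low < high && high < sampling_rate / 2))
    stop("need 0 < low < high < sampling_rate/2")
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  minlen <- 3 * (2 * order + 1)
  if (nrow(xm) <= minlen)
    stop(sprintf("series too short to filter: need more than %d samples", minlen))
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2), type = "pass")
  out <- apply(xm, 2, function(col) signal::filtfilt(bf, col))
  if (vec) as.vector(out) else out
}

#' Default haemoglobin extinction coefficients
#'
#' Molar extinction coefficients (1/(mM*cm)) of oxy- and deoxyhemoglobin
#' at 760 and 850 nm, from the compiled in-vitro spectra of Cope (1991) /
#' Gratzer as commonly tabulated in fNIRS toolboxes. Rows are wavelengths
#' (760, 850 nm), columns chromophores (HbO2, HbR). Override to use a
#' different table.
#'
#' @return A 2x2 numeric matrix with dimnames.
#' @export
default_extinction <- function() {
  matrix(c(0.5864, 1.5485,
           1.0584, 0.7811),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO2", "HbR")))
}

#' Modified Beer-Lambert conversion to concentration changes
#'
#' Converts two-wavelength intensities to oxy-/deoxyhemoglobin
#' concentration changes. Optical density changes are computed against a
#' whole-series baseline, `dOD(t) = -log10(I(t) / I_baseline)`, and the
#' 2x2 extinction system is solved per channel with wavelength-specific
#' differential pathlength factors. The default baseline is the geometric
#' mean intensity (equivalently the arithmetic mean in optical-density
#' space), which makes the conversion exactly linear and invertible and
#' yields concentration series with zero mean per channel; the arithmetic
#' mean intensity (`baseline = "mean"`) differs only at second order in
#' the optical-density excursions.
#'
#' @param raw A [raw_recording()].
#' @param dpf Differential pathlength factors per wavelength, default
#'   `c(7.25, 6.38)` for (760, 850) nm.
#' @param extinction 2x2 matrix, rows = wavelengths, cols = (HbO2, HbR);
#'   see [default_extinction()].
#' @param distance Source-detector distance in mm (default 30).
#' @param baseline `"geomean"` (default) or `"mean"`.
#' @return A list of class `hbo2_series`: `values` (time x channel HbO2,
#'   micromolar), `hbr` (same for HbR), `sampling_rate`, `montage`,
#'   `baseline_convention`.
#' @export
mbll <- function(raw, dpf = c(7.25, 6.38), extinction = default_extinction(),
                 distance = 30, baseline = c("geomean", "mean")) {
  stopifnot(inherits(raw, "raw_recording"))
  baseline <- match.arg(baseline)
  x <- raw$intensities
  if (any(!is.finite(x)) || any(x <= 0))
    stop("mbll requires strictly positive, finite intensities")
  E <- as.matrix(extinction)
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  if (length(dpf) != dim(x)[3]) stop("need one DPF per wavelength")
  n <- dim(x)[1]; nch <- dim(x)[2]
  path_cm <- (distance / 10) * dpf
  hbo2 <- matrix(NA_real_, n, nch)
  hbr <- matrix(NA_real_, n, nch)
  for (j in seq_len(nch)) {
    od <- matrix(NA_real_, n, 2)
    for (w in 1:2) {
      iw <- x[, j, w]
      ibase <- if (baseline == "geomean") exp(mean(log(iw))) else mean(iw)
      od[, w] <- -log10(iw / ibase) / path_cm[w]
    }
    conc <- t(solve(E, t(od))) * 1000          # uM
    hbo2[, j] <- conc[, 1]
    hbr[, j] <- conc[, 2]
  }
  structure(list(values = hbo2, hbr = hbr,
                 sampling_rate = raw$sampling_rate, montage = raw$montage,
                 baseline_convention = baseline),
            class = "hbo2_series")
}

#' @export
print.hbo2_series <- function(x, ...) {
  cat(sprintf("<hbo2_series> %d samples x %d channels, %.2f Hz, baseline '%s'\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              x$baseline_convention))
  invisible(x)
}

#' Full preprocessing of a raw dyad
#'
#' Quality-screens both subjects' raw intensities, converts them to HbO2
#' via the modified Beer-Lambert law, and band-passes the concentration
#' series to the haemodynamic band. Because both the band-pass and the
#' extinction-system solve are linear, filtering the optical densities or
#' the concentrations is mathematically identical; `filter_stage = "raw"`
#' instead filters the intensities before the logarithm.
#'
#' @param raw A `raw_dyad` (see [render_raw_intensities()]) or a list with
#'   `raw_recording` elements `teacher` and `student`.
#' @param low,high Band edges in Hz.
#' @param dpf,extinction,distance,baseline Passed to [mbll()].
#' @param filter_stage `"concentration"` (default, equivalent to filtering
#'   optical density) or `"raw"`.
#' @param qc Apply [quality_screen()] and error when a channel fails
#'   (default `TRUE`); set `FALSE` to skip.
#' @param id Dyad id for the result.
#' @return A [dyad_recording()] at stage `"hbo2"`, with QC reports in
#'   `attr(, "qc")`.
#' @export
preprocess_dyad <- function(raw, low = 0.01, high = 0.2,
                            dpf = c(7.25, 6.38),
                            extinction = default_extinction(),
                            distance = 30, baseline = "geomean",
                            filter_stage = c("concentration", "raw"),
                            qc = TRUE, id = NULL) {
  filter_stage <- match.arg(filter_stage)
  if (is.null(id)) id <- if (!is.null(raw$id)) raw$id else "dyad"
  qcrep <- list()
  one <- function(rr, who) {
    stopifnot(inherits(rr, "raw_recording"))
    if (qc) qcrep[[who]] <<- quality_screen(rr)
    if (filter_stage == "raw") {
      fi <- rr$intensities
      for (w in seq_len(dim(fi)[3]))
        fi[, , w] <- bandpass_filter(fi[, , w], rr$sampling_rate, low, high) +
          rep(colMeans(fi[, , w]), each = dim(fi)[1])
      rr$intensities <- fi
      mbll(rr, dpf, extinction, distance, baseline)$values
    } else {
      h <- mbll(rr, dpf, extinction, distance, baseline)$values
      bandpass_filter(h, rr$sampling_rate, low, high)
    }
  }
  teacher <- one(raw$teacher, "teacher")
  student <- one(raw$student, "student")
  out <- dyad_recording(teacher, student, raw$teacher$sampling_rate,
                        raw$teacher$montage, stage = "hbo2",
                        ground_truth = raw$ground_truth, id = id)
  attr(out, "qc") <- qcrep
  out
}
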