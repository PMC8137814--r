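#' Default 18-channel montage
#'
#' Builds the channel table used throughout the package: channels 1-8 over
#' the prefrontal cortex (PFC) and channels 9 onward over the
#' temporo-parietal junction (TPJ), the layout both members of a dyad wear.
#'
#' @param n_channels Number of channels per subject (default 18).
#' @return A data.frame with columns `channel` (integer id) and `region`
#'   (factor, `"PFC"` or `"TPJ"`).
#' @export
#' @examples
#' default_montage()
default_montage <- function(n_channels = 18L) {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L)
  region <- ifelse(seq_len(n_channels) <= min(8L, n_channels), "PFC", "TPJ")
  data.frame(channel = seq_len(n_channels),
             region = factor(region, levels = c("PFC", "TPJ")))
}

validate_montage <- function(montage, n_channels) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "region") %in% names(montage)))
  if (anyDuplicated(montage$channel))
    stop("montage channel ids must be unique")
  if (!all(as.character(montage$region) %in% c("PFC", "TPJ")))
    stop("montage regions must be 'PFC' or 'TPJ'")
  if (nrow(montage) != n_channels)
    stop(sprintf("montage has %d channels but data has %d columns",
                 nrow(montage), n_channels))
  invisible(montage)
}

#' Paired dyad recording
#'
#' Container for one teacher-student dyad: two time x channel matrices on a
#' common clock, plus montage and sampling metadata. This is the object the
#' fitting and inference stages consume (at the HbO2 stage) and that the
#' simulator produces.
#'
#' @param teacher,student Numeric matrices, time in rows, channels in
#'   columns; must share dimensions.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage Channel table as from [default_montage()].
#' @param stage Processing stage tag, `"hbo2"` for concentration-change
#'   series (micromolar).
#' @param ground_truth Optional list describing simulated coupling (see
#'   [generate_dyad()]); `NULL` for real data.
#' @param id Dyad identifier used in result tables.
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(teacher, student, sampling_rate,
                           montage = default_montage(ncol(teacher)),
                           stage = "hbo2", ground_truth = NULL,
                           id = "dyad") {
  teacher <- as.matrix(teacher)
  student <- as.matrix(student)
  if (!all(dim(teacher) == dim(student)))
    stop("teacher and student series must have identical dimensions")
  if (nrow(teacher) < 2L) stop("recordings need at least 2 samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (!all(is.finite(teacher)) || !all(is.finite(student)))
    stop("recordings must be finite")
  validate_montage(montage, ncol(teacher))
  structure(list(teacher = teacher, student = student,
                 sampling_rate = sampling_rate, montage = montage,
                 stage = stage, ground_truth = ground_truth, id = id),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording '%s'> %d samples x %d channels/subject, %.2f Hz (%.1f min), stage '%s'\n",
              x$id, nrow(x$teacher), ncol(x$teacher), x$sampling_rate,
              nrow(x$teacher) / x$sampling_rate / 60, x$stage))
  if (!is.null(x$ground_truth)) {
    cp <- x$ground_truth$coupled_channel_pairs
    if (NROW(cp) == 0) cat("  simulated null dyad (no coupled channel pairs)\n")
    else cat(sprintf("  simulated, %d coupled teacher->student channel pair(s)\n", NROW(cp)))
  }
  invisible(x)
}
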