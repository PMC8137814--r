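#' Write an HbO2 time x channel matrix as TSV
#'
#' Tab-separated text with a header row of channel ids (`ch1` ... `chN`),
#' one row per sample.
#'
#' @param values Numeric matrix, time x channel.
#' @param path Output file path.
#' @export
write_hbo2_tsv <- function(values, path) {
  values <- as.matrix(values)
  colnames(values) <- paste0("ch", seq_len(ncol(values)))
  utils::write.table(values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an HbO2 TSV written by [write_hbo2_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix, time x channel.
#' @export
read_hbo2_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write a simulated dyad to a directory
#'
#' Writes `teacher.tsv` and `student.tsv` (time x channel HbO2), a
#' `meta.json` (sampling rate, montage, stage, id) and, when present, a
#' `ground_truth.json` sidecar with the coupled channel pairs, gain
#' matrix and per-channel SNR.
#'
#' @param dyad A [dyad_recording()].
#' @param dir Output directory (created if needed).
#' @export
write_dyad <- function(dyad, dir) {
  stopifnot(inherits(dyad, "dyad_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hbo2_tsv(dyad$teacher, file.path(dir, "teacher.tsv"))
  write_hbo2_tsv(dyad$student, file.path(dir, "student.tsv"))
  meta <- list(id = dyad$id, sampling_rate = dyad$sampling_rate,
               stage = dyad$stage,
               montage = list(channel = dyad$montage$channel,
                              region = as.character(dyad$montage$region)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  gt <- dyad$ground_truth
  if (!is.null(gt)) {
    sidecar <- list(
      coupled_channel_pairs = if (NROW(gt$coupled_channel_pairs))
        apply(gt$coupled_channel_pairs, 1, function(r)
          list(teacher_channel = unname(r[1]), student_channel = unname(r[2])))
      else list(),
      coupling_gain = gt$coupling_gain,
      snr = gt$snr)
    jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dyad directory written by [write_dyad()]
#'
#' @param dir Directory path.
#' @return A [dyad_recording()] (without simulation internals; the
#'   ground-truth sidecar, if present, is attached as parsed JSON).
#' @export
read_dyad <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  teacher <- read_hbo2_tsv(file.path(dir, "teacher.tsv"))
  student <- read_hbo2_tsv(file.path(dir, "student.tsv"))
  montage <- data.frame(channel = meta$montage$channel,
                        region = factor(meta$montage$region,
                                        levels = c("PFC", "TPJ")))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  dyad_recording(teacher, student, meta$sampling_rate, montage,
                 stage = meta$stage, ground_truth = gt, id = meta$id)
}

#' Write a results table as TSV
#'
#' @param results Results data.frame (see [evaluate_coupling()]).
#' @param path Output file path.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
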