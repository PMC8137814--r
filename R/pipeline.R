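# canonical-deparse multiplicative string hash so every output can embed a
# stable fingerprint of the configuration that produced it
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
                        sep = "=", collapse = ";"), "}")
    } else paste(format(x, digits = 15), collapse = ",")
  }
  s <- utf8ToInt(canon(config))
  h <- 2166136261
  for (b in s) h <- ((h + b) * 16777619) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Run configuration for a multi-dyad pipeline
#'
#' Collects every stage parameter of a simulate - preprocess - fit -
#' evaluate run in one validated, serializable list. All randomness
#' derives from the single master `seed`, so two runs with the same
#' configuration are bit-for-bit identical.
#'
#' @param n_dyads Number of dyads to simulate (default 5).
#' @param seed Master seed.
#' @param duration,sampling_rate,n_channels Recording geometry (defaults
#'   900 s at 7.81 Hz, 18 channels).
#' @param coupled_channels Student channels receiving a coupled signal
#'   from the same-numbered teacher channel (default `c(9, 10, 11)`, in
#'   the TPJ block); use `integer(0)` for null dyads.
#' @param gain Coupling gain on those pairs (default 1).
#' @param snr Student signal-to-noise ratio on coupled channels (default 1).
#' @param use_raw Render raw two-wavelength intensities and run the full
#'   preprocessing chain (default `TRUE`); otherwise band-pass the
#'   simulated HbO2 directly.
#' @param low,high Filter band (Hz).
#' @param dpf Differential pathlength factors.
#' @param distance Source-detector distance, mm.
#' @param families Model families to fit.
#' @param fraction Training fraction.
#' @param epsilon,cost SVR hyperparameters.
#' @param B Bootstrap replicates (>= 100).
#' @param alpha Significance level.
#' @param acf_threshold,max_lag Block-length estimation settings.
#' @param fdr_scope `"dyad"` (adjust within each dyad x family, default)
#'   or `"global"` (one family-wise adjustment across all dyads).
#' @param figures Also write a significance-map figure per dyad when an
#'   output directory is given (default `FALSE`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_dyads = 5L, seed = 1L, duration = 900,
                       sampling_rate = 7.81, n_channels = 18L,
                       coupled_channels = c(9L, 10L, 11L), gain = 1,
                       snr = 1, use_raw = TRUE, low = 0.01, high = 0.2,
                       dpf = c(7.25, 6.38), distance = 30,
                       families = c("SVR", "OLS"), fraction = 0.5,
                       epsilon = 0.1, cost = 1, B = 1000L, alpha = 0.01,
                       acf_threshold = 0.05, max_lag = 300,
                       fdr_scope = c("dyad", "global"), figures = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  families <- match.arg(families, c("SVR", "OLS"), several.ok = TRUE)
  if (n_dyads < 1) stop("n_dyads must be >= 1")
  if (B < 100) stop("B must be at least 100 for a p-value report")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (length(coupled_channels) > 0 &&
      (any(coupled_channels < 1) || any(coupled_channels > n_channels)))
    stop("coupled_channels out of range")
  n_train <- ceiling(fraction * round(duration * sampling_rate))
  if (n_train <= 2 * max_lag)
    stop(sprintf(paste("training segment (%d samples) must exceed 2*max_lag = %d;",
                       "lengthen duration or reduce max_lag"),
                 n_train, 2 * max_lag))
  cfg <- list(n_dyads = as.integer(n_dyads), seed = as.integer(seed),
              duration = duration, sampling_rate = sampling_rate,
              n_channels = as.integer(n_channels),
              coupled_channels = as.integer(coupled_channels),
              gain = gain, snr = snr, use_raw = isTRUE(use_raw),
              low = low, high = high, dpf = dpf, distance = distance,
              families = families, fraction = fraction, epsilon = epsilon,
              cost = cost, B = as.integer(B), alpha = alpha,
              acf_threshold = acf_threshold, max_lag = max_lag,
              fdr_scope = fdr_scope, figures = isTRUE(figures))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [run_config()] arguments and
#' validates it.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' Execute the full cross-brain coupling pipeline
#'
#' For each dyad: simulate with known ground truth (coupled pairs on the
#' diagonal of the configured channels), optionally render raw
#' two-wavelength intensities and push them through QC + modified
#' Beer-Lambert conversion, band-pass to the haemodynamic band, fit the
#' SVR/OLS model grid on the first half, and evaluate held-out Spearman
#' accuracy against the block-bootstrap null. Results are pooled and
#' summarized as "x / (channels x dyads)" significance counts per family.
#'
#' @param config A [run_config()], or a YAML path accepted by
#'   [read_run_config()].
#' @param out_dir Optional directory; when given, writes per-dyad data,
#'   `results.tsv`, `summary.json` and `config.json` (all embedding the
#'   config hash), plus significance-map PNGs when `figures` is enabled.
#' @param verbose Print per-stage progress (default `FALSE`).
#' @return An object of class `run_report`: `results` (pooled table),
#'   `summary` (per-family counts), `config`, `hash`, `lags` (block
#'   length per dyad), `fits` and `tests` (per-dyad objects).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))
  say <- function(...) if (verbose) message(sprintf(...))

  G <- matrix(0, config$n_channels, config$n_channels)
  for (j in config$coupled_channels) G[j, j] <- config$gain

  all_results <- list(); fits <- list(); tests <- list()
  lags <- integer(config$n_dyads)
  for (d in seq_len(config$n_dyads)) {
    id <- sprintf("dyad%02d", d)
    say("[%s] simulate", id)
    scfg <- sim_config(n_channels = config$n_channels,
                       sampling_rate = config$sampling_rate,
                       duration = config$duration, coupling_gain = G,
                       student_snr = config$snr,
                       seed = config$seed + 1000L * d)
    dyad <- generate_dyad(scfg, id = id)
    if (config$use_raw) {
      say("[%s] preprocess (raw -> MBLL -> band-pass)", id)
      raw <- render_raw_intensities(dyad, dpf = config$dpf,
                                    distance = config$distance)
      dyad <- preprocess_dyad(raw, low = config$low, high = config$high,
                              dpf = config$dpf, distance = config$distance,
                              id = id)
      dyad$ground_truth <- raw$ground_truth
    } else {
      dyad$teacher <- bandpass_filter(dyad$teacher, dyad$sampling_rate,
                                      config$low, config$high)
      dyad$student <- bandpass_filter(dyad$student, dyad$sampling_rate,
                                      config$low, config$high)
    }
    say("[%s] fit %s", id, paste(config$families, collapse = "+"))
    fit <- fit_coupling(dyad, families = config$families,
                        fraction = config$fraction,
                        epsilon = config$epsilon, cost = config$cost)
    say("[%s] evaluate (B = %d)", id, config$B)
    ev <- evaluate_coupling(fit, B = config$B, alpha = config$alpha,
                            acf_threshold = config$acf_threshold,
                            max_lag = config$max_lag,
                            seed = config$seed + 1000L * d + 1L)
    lags[d] <- ev$lag$lag
    all_results[[d]] <- ev$results
    fits[[id]] <- fit; tests[[id]] <- ev
    if (!is.null(out_dir)) {
      dd <- file.path(out_dir, id)
      write_dyad(dyad, dd)
      if (config$figures) {
        grDevices::png(file.path(dd, "significance_map.png"), 900, 600)
        plot(ev)
        grDevices::dev.off()
      }
    }
  }
  results <- do.call(rbind, all_results)
  if (config$fdr_scope == "global") {
    for (fam in unique(results$family)) {
      i <- results$family == fam
      results$q[i] <- fdr_adjust(results$p[i])
      results$sig_fdr[i] <- is.finite(results$q[i]) & results$q[i] <= config$alpha
    }
  }
  summ <- summarize_run(results, alpha = config$alpha)
  report <- structure(list(results = results, summary = summ,
                           config = config, hash = hash, lags = lags,
                           fits = fits, tests = tests),
                      class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res_out <- cbind(results, config_hash = hash)
    write_results_tsv(res_out, file.path(out_dir, "results.tsv"))
    jsonlite::write_json(c(list(config_hash = hash),
                           split(summ, seq_len(nrow(summ)))),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Summarize significance counts across dyads
#'
#' Counts significant channel-pairs per model family at the uncorrected
#' and FDR-corrected levels, with denominators equal to channels x dyads
#' actually evaluated, formatted as "x/N".
#'
#' @param results Pooled results table from [run_pipeline()] or rbind-ed
#'   [evaluate_coupling()] tables.
#' @param alpha Significance level the flags were computed at; all rows
#'   must share it (mixed levels are an error when flags are recomputed).
#' @return A data.frame with one row per family: `family`, `n_tests`,
#'   `n_sig_uncorrected`, `n_sig_fdr`, `label_uncorrected`, `label_fdr`.
#' @export
summarize_run <- function(results, alpha = 0.01) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  recount_unc <- is.finite(results$p) & results$p <= alpha
  if (any(recount_unc != results$sig_uncorrected, na.rm = TRUE))
    stop("significance flags inconsistent with alpha: mixed levels across dyads?")
  out <- do.call(rbind, lapply(unique(results$family), function(fam) {
    r <- results[results$family == fam, ]
    n <- nrow(r)
    nu <- sum(r$sig_uncorrected, na.rm = TRUE)
    nf <- sum(r$sig_fdr, na.rm = TRUE)
    data.frame(family = fam, n_tests = n, n_sig_uncorrected = nu,
               n_sig_fdr = nf,
               label_uncorrected = sprintf("%d/%d", nu, n),
               label_fdr = sprintf("%d/%d", nf, n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d dyad(s), %d channels, B = %d, alpha = %g, config %s\n",
              x$config$n_dyads, x$config$n_channels, x$config$B,
              x$config$alpha, x$hash))
  cat(sprintf("  block lengths: %s\n", paste(x$lags, collapse = ", ")))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %s significant uncorrected, %s after FDR\n",
                x$summary$family[i], x$summary$label_uncorrected[i],
                x$summary$label_fdr[i]))
  invisible(x)
}
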