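#' Spearman rank correlation
#'
#' Rank correlation between two equal-length series, with average ranks
#' for ties. Used as the accuracy metric between predicted and observed
#' held-out student series because it is robust to outliers and invariant
#' under monotone transforms.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3) stop("need at least 3 samples")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("inputs must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Spearman correlation undefined for constant input")
  stats::cor(a, b, method = "spearman")
}

#' Autocorrelation-based block length for the bootstrap
#'
#' For each teacher channel, finds the smallest positive lag at which the
#' absolute sample autocorrelation falls to (or below) `threshold` --
#' i.e. where the series has decorrelated -- then aggregates the
#' per-channel lags into a single block length per dyad (median across
#' channels, rounded up). This lag sets the block size of the moving-block
#' shuffle so that within-block short-range dependence is preserved while
#' the alignment between the two subjects is destroyed.
#'
#' @param teacher Numeric matrix (training segment, time x channels) or
#'   vector.
#' @param threshold Near-zero band for the ACF (default 0.05).
#' @param max_lag Largest lag searched (default 300 samples); the segment
#'   must be longer than `2 * max_lag`.
#' @return An object of class `lag_estimate`: `lag` (integer),
#'   `per_channel`, `threshold`, `aggregation`.
#' @export
find_block_lag <- function(teacher, threshold = 0.05, max_lag = 300) {
  x <- as.matrix(teacher)
  n <- nrow(x)
  if (n <= 2 * max_lag)
    stop(sprintf("segment length %d must exceed 2*max_lag = %d; reduce max_lag",
                 n, 2 * max_lag))
  per <- vapply(seq_len(ncol(x)), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE)$acf[-1]
    k <- which(abs(a) <= threshold)
    if (length(k) == 0)
      stop(sprintf("channel %d: |ACF| never reaches %.3g within %d lags; increase max_lag",
                   j, threshold, max_lag))
    k[1]
  }, numeric(1))
  structure(list(lag = as.integer(ceiling(stats::median(per))),
                 per_channel = as.integer(per), threshold = threshold,
                 aggregation = "median (rounded up)"),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> block length %d samples (%s of %d channels, |ACF| <= %.3g)\n",
              x$lag, x$aggregation, length(x$per_channel), x$threshold))
  invisible(x)
}

#' Moving-block shuffle of a multichannel series
#'
#' Cuts the series into `floor(n / lag)` contiguous blocks of `lag`
#' samples (trailing remainder samples are dropped), permutes the block
#' order uniformly at random, and rebinds. The same permutation is applied
#' jointly to all columns, preserving the inter-channel covariance
#' structure the prediction models depend on. With `lag = n` there is a
#' single block and the output equals the (full-length) input.
#'
#' @param x Numeric matrix (time x channels) or vector.
#' @param lag Block length in samples, `1 <= lag <= n`. `lag = 1` reduces
#'   to an i.i.d. permutation of samples.
#' @param seed Optional integer seed for the permutation.
#' @return Shuffled matrix with `floor(n / lag) * lag` rows; the applied
#'   block permutation is stored in `attr(, "permutation")`.
#' @export
block_shuffle <- function(x, lag, seed = NULL) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  n <- nrow(xm)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1")
  if (lag > n) stop(sprintf("lag %d exceeds series length %d", lag, n))
  nb <- n %/% lag
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nb)
  idx <- rep((perm - 1L) * lag, each = lag) + seq_len(lag)
  out <- xm[idx, , drop = FALSE]
  attr(out, "permutation") <- perm
  if (vec) {
    out <- as.vector(out)
    attr(out, "permutation") <- perm
  }
  out
}

# Shared bootstrap workhorse. One block-shuffled teacher series per
# replicate is reused across all requested response channels and families
# (the marginal null of each channel is unchanged, and the expensive part
# -- the shuffle and, for OLS, one multi-response QR -- is paid once).
# Returns rhos[B, channel, family] plus per-replicate seeds and failures.
boot_correlations <- function(teacher, student, boundary, lag, B,
                              families, channels, epsilon = 0.1, cost = 1,
                              standardize = TRUE, tolerance = 0.001,
                              seed = 1L) {
  n <- nrow(teacher)
  nb <- n %/% lag
  nkeep <- nb * lag
  if (boundary >= nkeep - 2)
    stop("block-truncated series leaves no usable test segment")
  ntest <- nkeep - boundary
  y_train <- student[seq_len(boundary), channels, drop = FALSE]
  y_test <- student[(boundary + 1):n, channels, drop = FALSE]
  # replicate test segments are trimmed to the block-truncated length
  r_test <- apply(y_test[seq_len(ntest), , drop = FALSE], 2, rank)

  set.seed(as.integer(seed %% 2000000000L))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  rhos <- array(NA_real_, dim = c(B, length(channels), length(families)),
                dimnames = list(NULL, paste0("ch", channels), families))
  failures <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    tsh <- block_shuffle(teacher, lag)
    x_tr <- tsh[seq_len(boundary), , drop = FALSE]
    x_ts <- tsh[(boundary + 1):nkeep, , drop = FALSE]
    failed <- FALSE
    if ("OLS" %in% families) {
      Z <- cbind(1, x_tr)
      beta <- tryCatch(solve(crossprod(Z), crossprod(Z, y_train)),
                       error = function(e) NULL)
      if (is.null(beta)) failed <- TRUE
      else {
        pr <- cbind(1, x_ts) %*% beta
        for (jj in seq_along(channels)) {
          if (stats::sd(pr[, jj]) == 0) { failed <- TRUE; break }
          rhos[b, jj, "OLS"] <- stats::cor(rank(pr[, jj]), r_test[, jj])
        }
      }
    }
    if (!failed && "SVR" %in% families) {
      for (jj in seq_along(channels)) {
        sp <- tryCatch(
          fit_svr(y_train[, jj], x_tr, epsilon = epsilon, cost = cost,
                  standardize = standardize, tolerance = tolerance),
          error = function(e) NULL)
        if (is.null(sp)) { failed <- TRUE; break }
        pv <- predict(sp, x_ts)
        if (stats::sd(pv) == 0) { failed <- TRUE; break }
        rhos[b, jj, "SVR"] <- stats::cor(rank(pv), r_test[, jj])
      }
    }
    if (failed) {
      failures <- failures + 1L
      rhos[b, , ] <- NA_real_
    }
  }
  if (failures > 0.05 * B)
    stop(sprintf("%d of %d bootstrap replicates failed (> 5%%)", failures, B))
  list(rhos = rhos, seeds = rep_seeds, failures = failures,
       lag = lag, n_blocks = nb)
}

#' Block-bootstrap null distribution for one channel and family
#'
#' Builds the null distribution of the prediction accuracy under "no
#' cross-brain coupling": in each of `B` replicates the teacher's full
#' series is block-shuffled (destroying its alignment with the student
#' while keeping its autocorrelation), the model is refitted on the
#' shuffled training half against the real student training series, its
#' prediction on the shuffled test half is correlated (Spearman) with the
#' real student test series, and the `B` coefficients are collected. The
#' student series is never permuted.
#'
#' @param dyad A [dyad_recording()].
#' @param family `"SVR"` or `"OLS"`.
#' @param response_channel Student channel (1-based).
#' @param B Number of replicates (>= 100; the reference protocol uses
#'   1,000).
#' @param lag Block length; `NULL` (default) estimates it from the
#'   teacher's training segment via [find_block_lag()].
#' @param fraction Training fraction.
#' @param seed Master seed; per-replicate seeds are spawned from it
#'   deterministically and returned.
#' @param epsilon,cost,standardize,tolerance SVR settings.
#' @param acf_threshold,max_lag Passed to [find_block_lag()] when `lag`
#'   is estimated.
#' @return Object of class `null_distribution`: `coefficients` (length
#'   B), `lag`, `n_blocks`, `seeds`, `family`, `response_channel`,
#'   `failures`.
#' @export
bootstrap_null <- function(dyad, family = c("SVR", "OLS"),
                           response_channel = 1L, B = 1000L, lag = NULL,
                           fraction = 0.5, seed = 1L, epsilon = 0.1,
                           cost = 1, standardize = TRUE, tolerance = 0.001,
                           acf_threshold = 0.05, max_lag = 300) {
  stopifnot(inherits(dyad, "dyad_recording"))
  family <- match.arg(family)
  if (B < 100) stop("B must be at least 100 for a p-value report")
  sp <- split_series(dyad, fraction)
  if (is.null(lag))
    lag <- find_block_lag(sp$teacher_train, acf_threshold, max_lag)$lag
  bc <- boot_correlations(dyad$teacher, dyad$student, sp$boundary, lag, B,
                          family, response_channel, epsilon, cost,
                          standardize, tolerance, seed)
  structure(list(coefficients = as.vector(bc$rhos[, 1, 1]), lag = bc$lag,
                 n_blocks = bc$n_blocks, seeds = bc$seeds, family = family,
                 response_channel = response_channel,
                 failures = bc$failures),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s channel %d: B = %d, block length %d (%d blocks)\n",
              x$family, x$response_channel, length(x$coefficients), x$lag,
              x$n_blocks))
  invisible(x)
}

#' Bootstrap p-value from a null distribution
#'
#' One-sided p-value by the ratio rule: the number of bootstrap
#' coefficients strictly greater than the observed coefficient, divided
#' by the number of bootstrap coefficients. The optional bias-corrected
#' variant `(count + 1) / (B + 1)` never returns exactly zero but is off
#' by default to keep the literal ratio rule.
#'
#' @param observed Observed Spearman coefficient.
#' @param null A `null_distribution` or numeric vector of null
#'   coefficients.
#' @param corrected Use the +1/+1 estimator (default `FALSE`).
#' @return p-value in [0, 1].
#' @export
bootstrap_pvalue <- function(observed, null, corrected = FALSE) {
  coefs <- if (inherits(null, "null_distribution")) null$coefficients else null
  coefs <- coefs[is.finite(coefs)]
  if (length(coefs) == 0) stop("empty null distribution")
  ct <- sum(coefs > observed)
  if (corrected) (ct + 1) / (length(coefs) + 1) else ct / length(coefs)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values for a family of bootstrap p-values. The
#' default scope downstream is the channels of one dyad within one model
#' family; a global scope across dyads is available in
#' [summarize_run()].
#'
#' @param p Numeric p-values in [0, 1] (NAs preserved).
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance evaluation of a fitted coupling grid
#'
#' Scores every fitted model by the Spearman correlation between its
#' prediction and the student's held-out series, then assesses
#' significance against the block-bootstrap null: the block length is the
#' first near-zero crossing of the teacher's training-segment
#' autocorrelation (median across channels), each replicate refits on a
#' block-shuffled teacher, and the one-sided bootstrap p-values are
#' FDR-adjusted (Benjamini-Hochberg) within each model family across the
#' dyad's channels.
#'
#' @param fit A [fit_coupling()] result.
#' @param B Bootstrap replicates (default 1000, >= 100).
#' @param alpha Significance level for the flags (default 0.01).
#' @param acf_threshold Near-zero ACF band (default 0.05).
#' @param max_lag Largest lag searched (default 300).
#' @param lag Block length override; `NULL` estimates it. `lag = 1` gives
#'   the naive i.i.d. permutation null (for diagnostics -- it is
#'   anti-conservative on autocorrelated data).
#' @param channels Response channels to evaluate (default: all with a
#'   fitted model).
#' @param seed Master seed for the bootstrap.
#' @param corrected Use the +1/+1 p-value estimator (default `FALSE`).
#' @param keep_null Retain the full null coefficient arrays (default
#'   `FALSE`).
#' @return Object of class `coupling_test`: `results` (data.frame with
#'   columns dyad, channel, region, family, rho, p, q, sig_uncorrected,
#'   sig_fdr), `lag` (a `lag_estimate`), `B`, `alpha`, and optionally
#'   `null`.
#' @export
#' @examples
#' \donttest{
#' d <- generate_dyad(sim_config(duration = 90, seed = 3))
#' fit <- fit_coupling(d, families = "OLS")
#' ev <- evaluate_coupling(fit, B = 100, max_lag = 100, seed = 1)
#' ev
#' }
evaluate_coupling <- function(fit, B = 1000L, alpha = 0.01,
                              acf_threshold = 0.05, max_lag = 300,
                              lag = NULL, channels = NULL, seed = 1L,
                              corrected = FALSE, keep_null = FALSE) {
  stopifnot(inherits(fit, "coupling_fit"))
  if (B < 100) stop("B must be at least 100 for a p-value report")
  dyad <- fit$dyad
  sp <- fit$split
  lag_est <- if (is.null(lag))
    find_block_lag(sp$teacher_train, acf_threshold, max_lag)
  else
    structure(list(lag = as.integer(lag), per_channel = as.integer(lag),
                   threshold = acf_threshold, aggregation = "fixed"),
              class = "lag_estimate")

  nch <- ncol(dyad$student)
  fitted_ch <- sort(unique(unlist(lapply(fit$families, function(f)
    which(!vapply(fit$models[[f]], is.null, logical(1)))))))
  if (is.null(channels)) channels <- fitted_ch
  channels <- intersect(channels, fitted_ch)

  rows <- list()
  null_keep <- NULL
  if (length(channels) > 0) {
    hy <- fit$hyperparameters
    bc <- boot_correlations(dyad$teacher, dyad$student, sp$boundary,
                            lag_est$lag, B, fit$families, channels,
                            hy$epsilon, hy$cost, hy$standardize,
                            hy$tolerance, seed)
    if (keep_null) null_keep <- bc$rhos
    for (fam in fit$families) {
      p <- rep(NA_real_, nch); rho <- rep(NA_real_, nch)
      for (jj in seq_along(channels)) {
        j <- channels[jj]
        m <- fit$models[[fam]][[j]]
        if (is.null(m)) next
        pr <- predict(m, sp$teacher_test)
        rho[j] <- tryCatch(spearman_rho(pr, sp$student_test[, j]),
                           error = function(e) NA_real_)
        if (is.finite(rho[j]))
          p[j] <- bootstrap_pvalue(rho[j], bc$rhos[, jj, fam], corrected)
      }
      q <- rep(NA_real_, nch)
      q[channels] <- fdr_adjust(p[channels])
      for (j in channels) {
        rows[[length(rows) + 1]] <- data.frame(
          dyad = dyad$id, channel = j,
          region = as.character(dyad$montage$region[j]), family = fam,
          rho = rho[j], p = p[j], q = q[j],
          sig_uncorrected = is.finite(p[j]) && p[j] <= alpha,
          sig_fdr = is.finite(q[j]) && q[j] <= alpha,
          stringsAsFactors = FALSE)
      }
    }
  } else {
    warning("no fitted channels to evaluate; empty results table")
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dyad = character(0), channel = integer(0),
               region = character(0), family = character(0),
               rho = numeric(0), p = numeric(0), q = numeric(0),
               sig_uncorrected = logical(0), sig_fdr = logical(0))
  structure(list(results = results, lag = lag_est, B = B, alpha = alpha,
                 null = null_keep, montage = dyad$montage,
                 dyad_id = dyad$id),
            class = "coupling_test")
}

#' @export
print.coupling_test <- function(x, ...) {
  cat(sprintf("<coupling_test> dyad '%s': B = %d, block length %d, alpha = %g\n",
              x$dyad_id, x$B, x$lag$lag, x$alpha))
  for (fam in unique(x$results$family)) {
    r <- x$results[x$results$family == fam, ]
    cat(sprintf("  %s: %d/%d significant uncorrected, %d/%d after FDR\n",
                fam, sum(r$sig_uncorrected, na.rm = TRUE), nrow(r),
                sum(r$sig_fdr, na.rm = TRUE), nrow(r)))
  }
  invisible(x)
}

#' @export
summary.coupling_test <- function(object, ...) {
  print(object)
  cat("\n")
  print.data.frame(object$results, row.names = FALSE, digits = 3)
  invisible(object$results)
}

#' Channel-wise significance map
#'
#' Bar plot of the held-out Spearman correlation per channel, one panel
#' per model family, with significant channels highlighted (filled:
#' FDR-significant, hatched: uncorrected only) and the PFC/TPJ boundary
#' marked.
#'
#' @param x A `coupling_test`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.coupling_test <- function(x, ...) {
  fams <- unique(x$results$family)
  op <- graphics::par(mfrow = c(length(fams), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (fam in fams) {
    r <- x$results[x$results$family == fam, ]
    r <- r[order(r$channel), ]
    cols <- ifelse(r$sig_fdr, "firebrick",
                   ifelse(r$sig_uncorrected, "salmon", "grey80"))
    graphics::barplot(r$rho, names.arg = r$channel, col = cols,
                      border = NA, ylab = "Spearman rho", xlab = "channel",
                      main = sprintf("%s (dyad %s)", fam, x$dyad_id), ...)
    npfc <- sum(x$montage$region == "PFC")
    graphics::abline(v = npfc * 1.2 + 0.1, lty = 2)
    graphics::mtext("PFC | TPJ", side = 3, line = -1, adj = 0.02, cex = 0.8)
  }
  invisible(x)
}
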