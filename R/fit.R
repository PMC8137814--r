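#' Chronological train/test split of a dyad
#'
#' Splits both subjects' series at the same boundary: the first
#' `ceiling(fraction * n)` samples are the training segment, the remainder
#' the held-out test segment (train first, contiguous, disjoint, covering
#' the series). The default reproduces the 50/50 protocol: models are
#' learned on the first half of the interaction and scored on the second.
#'
#' @param dyad A [dyad_recording()].
#' @param fraction Training fraction in (0, 1), default 0.5. Odd lengths
#'   round the boundary up (ceiling), so n = 7 gives 4 train / 3 test.
#' @return A list with `teacher_train`, `teacher_test`, `student_train`,
#'   `student_test` and the `boundary` sample index.
#' @export
split_series <- function(dyad, fraction = 0.5) {
  stopifnot(inherits(dyad, "dyad_recording"))
  n <- nrow(dyad$teacher)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be strictly between 0 and 1 (both segments non-empty)")
  b <- ceiling(fraction * n)
  if (b < 1 || b >= n) stop("split leaves an empty train or test segment")
  list(teacher_train = dyad$teacher[seq_len(b), , drop = FALSE],
       teacher_test = dyad$teacher[(b + 1):n, , drop = FALSE],
       student_train = dyad$student[seq_len(b), , drop = FALSE],
       student_test = dyad$student[(b + 1):n, , drop = FALSE],
       boundary = b)
}

new_model_spec <- function(family, channel, weights, intercept,
                           hyper = NULL) {
  if (!all(is.finite(weights)) || !is.finite(intercept))
    stop("fitted parameters must be finite")
  structure(list(family = family, response_channel = channel,
                 weights = as.numeric(weights), intercept = intercept,
                 hyperparameters = hyper),
            class = "coupling_model_spec")
}

#' @export
print.coupling_model_spec <- function(x, ...) {
  cat(sprintf("<%s model, response channel %s> %d weights, intercept %.4g\n",
              x$family, as.character(x$response_channel),
              length(x$weights), x$intercept))
  invisible(x)
}

#' Ordinary least squares fit of one response channel
#'
#' Regresses one student channel on all teacher channels with an
#' intercept, by QR decomposition. A rank-deficient predictor matrix is a
#' hard error naming the collinear columns: silently pseudo-inverting
#' would hand the bootstrap a degenerate model.
#'
#' @param response Numeric vector (training segment of the student
#'   channel).
#' @param predictors Numeric matrix, training samples x teacher channels.
#' @param channel Response channel id stored in the result.
#' @return A `coupling_model_spec` with `weights` and `intercept`.
#' @export
fit_ols <- function(response, predictors, channel = NA_integer_) {
  predictors <- as.matrix(predictors)
  n <- length(response)
  if (nrow(predictors) != n) stop("response/predictor length mismatch")
  if (n < 20) stop("need at least 20 training samples")
  Z <- cbind(1, predictors)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- qz$pivot[(qz$rank + 1):ncol(Z)] - 1L
    stop(sprintf("rank-deficient predictors: collinear channel(s) %s",
                 paste(bad[bad > 0], collapse = ", ")))
  }
  beta <- qr.coef(qz, response)
  new_model_spec("OLS", channel, beta[-1], beta[1])
}

#' Linear epsilon-insensitive support vector regression fit
#'
#' Fits a linear-kernel epsilon-SVR for one response channel and extracts
#' the primal weights and intercept so predictions are a plain affine map
#' of the teacher channels. Predictors and response are standardized
#' internally by default (SVR solutions are scale-sensitive) and the
#' parameters un-scaled back to the original units for reporting. Default
#' hyperparameters epsilon = 0.1 and cost = 1 follow the defaults of the
#' e1071/libsvm implementation this wraps.
#'
#' @param response,predictors As in [fit_ols()].
#' @param epsilon Insensitivity-tube half-width (>= 0), default 0.1.
#' @param cost Box constraint C > 0, default 1.
#' @param standardize Standardize internally (default `TRUE`).
#' @param tolerance Solver termination tolerance (default 0.001).
#' @param channel Response channel id stored in the result.
#' @return A `coupling_model_spec` with hyperparameters recorded.
#' @export
fit_svr <- function(response, predictors, epsilon = 0.1, cost = 1,
                    standardize = TRUE, tolerance = 0.001,
                    channel = NA_integer_) {
  predictors <- as.matrix(predictors)
  if (nrow(predictors) != length(response))
    stop("response/predictor length mismatch")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (cost <= 0) stop("cost must be > 0")
  hyper <- list(epsilon = epsilon, cost = cost, standardize = standardize)
  p <- ncol(predictors)

  sy <- stats::sd(response)
  if (sy == 0)  # zero-loss, zero-norm optimum is exact
    return(new_model_spec("SVR", channel, rep(0, p), response[1], hyper))

  if (standardize) {
    mx <- colMeans(predictors)
    sx <- apply(predictors, 2, stats::sd)
    sx[sx == 0] <- 1
    X <- sweep(sweep(predictors, 2, mx), 2, sx, "/")
    my <- mean(response)
    y <- (response - my) / sy
  } else {
    X <- predictors; y <- response
    mx <- rep(0, p); sx <- rep(1, p); my <- 0; sy <- 1
  }
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
               epsilon = epsilon, cost = cost, scale = FALSE,
               tolerance = tolerance),
    error = function(e) stop(sprintf("SVR solver failed: %s", conditionMessage(e))))
  ws <- as.numeric(crossprod(fit$coefs, fit$SV))
  bs <- -fit$rho
  w <- sy * ws / sx
  b <- my + sy * (bs - sum(ws * mx / sx))
  new_model_spec("SVR", channel, w, b, hyper)
}

#' Predict a student channel from teacher test data
#'
#' Applies the fitted affine map `sum_i w_i T_i(t) + b` elementwise over
#' the supplied teacher samples.
#'
#' @param object A `coupling_model_spec`.
#' @param newdata Numeric matrix, samples x teacher channels; column count
#'   must match the model's weight vector.
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.coupling_model_spec <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    stop(sprintf("model has %d weights but newdata has %d channels",
                 length(object$weights), ncol(newdata)))
  as.vector(newdata %*% object$weights + object$intercept)
}

#' Fit the full cross-brain coupling model grid for a dyad
#'
#' For every student response channel, fits the requested model families
#' (linear SVR and/or OLS) on the training half, each regressing that
#' channel on all of the teacher's channels. A clean 18-channel dyad with
#' both families yields 36 model specifications. Channels excluded by
#' quality control, and per-channel fit failures, are recorded as skips
#' rather than aborting the grid.
#'
#' @param dyad A [dyad_recording()] at the HbO2 stage.
#' @param families Character subset of `c("SVR", "OLS")`.
#' @param fraction Training fraction, see [split_series()].
#' @param epsilon,cost,standardize,tolerance SVR settings, see
#'   [fit_svr()].
#' @param exclude_channels Integer response channels to skip (e.g. from a
#'   QC report).
#' @return An object of class `coupling_fit` holding the model grid, the
#'   split, skip records, and the dyad.
#' @export
#' @examples
#' d <- generate_dyad(sim_config(duration = 90, seed = 3))
#' fit <- fit_coupling(d)
#' fit
#' head(coef(fit)[, 1:5])
fit_coupling <- function(dyad, families = c("SVR", "OLS"), fraction = 0.5,
                         epsilon = 0.1, cost = 1, standardize = TRUE,
                         tolerance = 0.001, exclude_channels = integer(0)) {
  stopifnot(inherits(dyad, "dyad_recording"))
  families <- match.arg(families, c("SVR", "OLS"), several.ok = TRUE)
  sp <- split_series(dyad, fraction)
  nch <- ncol(dyad$student)
  models <- stats::setNames(vector("list", length(families)), families)
  skipped <- data.frame(channel = integer(0), family = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (fam in families) {
    models[[fam]] <- vector("list", nch)
    for (j in seq_len(nch)) {
      if (j %in% exclude_channels) {
        skipped <- rbind(skipped, data.frame(channel = j, family = fam,
                                             reason = "excluded (QC)"))
        next
      }
      res <- tryCatch({
        if (fam == "OLS")
          fit_ols(sp$student_train[, j], sp$teacher_train, channel = j)
        else
          fit_svr(sp$student_train[, j], sp$teacher_train,
                  epsilon = epsilon, cost = cost,
                  standardize = standardize, tolerance = tolerance,
                  channel = j)
      }, error = function(e) conditionMessage(e))
      if (is.character(res))
        skipped <- rbind(skipped, data.frame(channel = j, family = fam,
                                             reason = res))
      else models[[fam]][[j]] <- res
    }
  }
  structure(list(models = models, skipped = skipped, split = sp,
                 fraction = fraction, families = families,
                 hyperparameters = list(epsilon = epsilon, cost = cost,
                                        standardize = standardize,
                                        tolerance = tolerance),
                 dyad = dyad),
            class = "coupling_fit")
}

n_models <- function(fit) {
  sum(vapply(fit$models, function(fam) sum(!vapply(fam, is.null, logical(1))),
             integer(1)))
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> dyad '%s': %d fitted models (%s) over %d channels\n",
              x$dyad$id, n_models(x), paste(x$families, collapse = " + "),
              ncol(x$dyad$student)))
  cat(sprintf("  train %d / test %d samples (fraction %.2f)\n",
              x$split$boundary, nrow(x$split$teacher_test), x$fraction))
  if (nrow(x$skipped) > 0)
    cat(sprintf("  %d channel fit(s) skipped\n", nrow(x$skipped)))
  invisible(x)
}

#' Coefficients of a fitted coupling grid
#'
#' @param object A `coupling_fit`.
#' @param ... Unused.
#' @return A data.frame with one row per fitted model: `family`,
#'   `channel`, `intercept`, and one `w<i>` column per teacher channel.
#' @export
coef.coupling_fit <- function(object, ...) {
  rows <- list()
  for (fam in object$families) {
    for (m in object$models[[fam]]) {
      if (is.null(m)) next
      r <- data.frame(family = fam, channel = m$response_channel,
                      intercept = m$intercept)
      w <- as.data.frame(t(m$weights))
      names(w) <- paste0("w", seq_along(m$weights))
      rows[[length(rows) + 1]] <- cbind(r, w)
    }
  }
  do.call(rbind, rows)
}

#' Predictions of the student's test-segment series
#'
#' @param object A `coupling_fit`.
#' @param family Model family to use (default the first fitted).
#' @param newdata Teacher matrix to predict from; defaults to the stored
#'   teacher test segment.
#' @param ... Unused.
#' @return Matrix, samples x response channels (NA columns for skipped
#'   channels).
#' @export
predict.coupling_fit <- function(object, family = object$families[1],
                                 newdata = NULL, ...) {
  family <- match.arg(family, object$families)
  if (is.null(newdata)) newdata <- object$split$teacher_test
  newdata <- as.matrix(newdata)
  nch <- length(object$models[[family]])
  out <- matrix(NA_real_, nrow(newdata), nch)
  for (j in seq_len(nch)) {
    m <- object$models[[family]][[j]]
    if (!is.null(m)) out[, j] <- predict(m, newdata)
  }
  colnames(out) <- paste0("ch", seq_len(nch))
  out
}

#' In-sample fitted values on the training segment
#'
#' @param object A `coupling_fit`.
#' @param family Model family.
#' @param ... Unused.
#' @return Matrix, training samples x response channels.
#' @export
fitted.coupling_fit <- function(object, family = object$families[1], ...) {
  predict(object, family = family, newdata = object$split$teacher_train)
}

#' Training residuals
#'
#' @inheritParams fitted.coupling_fit
#' @return Matrix of residuals, training samples x response channels.
#' @export
residuals.coupling_fit <- function(object, family = object$families[1], ...) {
  object$split$student_train - fitted(object, family = family)
}

#' Summary of held-out prediction accuracy
#'
#' Spearman rank correlation between each model's prediction and the
#' student's held-out test series, per channel and family (no inference;
#' see [evaluate_coupling()] for significance).
#'
#' @param object A `coupling_fit`.
#' @param ... Unused.
#' @return An object of class `summary.coupling_fit` (a data.frame with
#'   columns `family`, `channel`, `region`, `rho`).
#' @export
summary.coupling_fit <- function(object, ...) {
  rows <- list()
  for (fam in object$families) {
    pr <- predict(object, family = fam)
    for (j in seq_len(ncol(pr))) {
      rho <- if (all(is.na(pr[, j]))) NA_real_ else
        tryCatch(spearman_rho(pr[, j], object$split$student_test[, j]),
                 error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, channel = j,
        region = as.character(object$dyad$montage$region[j]), rho = rho)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary.coupling_fit", "data.frame")
  out
}

#' @export
print.summary.coupling_fit <- function(x, ...) {
  cat("Held-out Spearman correlation by channel and family\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
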