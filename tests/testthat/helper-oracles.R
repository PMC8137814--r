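# Independent oracles, written against the math rather than the package:
# an exact epsilon-SVR dual solved by KKT active-pattern enumeration, a
# brute-force Benjamini-Hochberg step-up, and the double-gamma response
# evaluated directly on the sample grid.

# Exact linear epsilon-SVR via the dual
#   max -1/2 b'Kb + y'b - eps*||b||_1  s.t.  sum(b) = 0, -C <= b_i <= C
# by enumerating, for every point, the five KKT states
# {b=-C, b in (-C,0), b=0, b in (0,C), b=C}, solving the stationarity
# system for each pattern and keeping the best feasible solution.
# Tractable up to ~8 points; the equality multiplier is the intercept.
svr_dual_oracle <- function(X, y, eps, C) {
  n <- length(y)
  K <- X %*% t(X)
  best <- NULL; bestobj <- -Inf
  states <- rep(1L, n)
  repeat {
    s <- states
    free <- which(s == 2L | s == 4L)
    b <- ifelse(s == 1L, -C, ifelse(s == 5L, C, 0))
    nf <- length(free)
    ok <- TRUE; mu <- NA_real_
    if (nf > 0) {
      A <- matrix(0, nf + 1, nf + 1); rhs <- numeric(nf + 1)
      ei <- ifelse(s[free] == 2L, eps, -eps)
      fixi <- which(s %in% c(1L, 5L))
      for (r in seq_len(nf)) {
        i <- free[r]
        A[r, seq_len(nf)] <- K[i, free]
        A[r, nf + 1] <- 1
        rhs[r] <- y[i] + ei[r] -
          (if (length(fixi)) sum(K[i, fixi] * b[fixi]) else 0)
      }
      A[nf + 1, seq_len(nf)] <- 1
      rhs[nf + 1] <- -sum(b)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) ok <- FALSE
      else { b[free] <- sol[seq_len(nf)]; mu <- sol[nf + 1] }
    } else if (abs(sum(b)) > 1e-10) ok <- FALSE
    if (ok) {
      g <- -as.vector(K %*% b) + y
      tol <- 1e-9
      if (any(s == 2L) && any(b[s == 2L] <= -C + tol | b[s == 2L] >= -tol)) ok <- FALSE
      if (ok && any(s == 4L) && any(b[s == 4L] <= tol | b[s == 4L] >= C - tol)) ok <- FALSE
      if (ok && nf == 0) {
        lo <- -Inf; hi <- Inf
        for (i in seq_len(n)) {
          if (s[i] == 1L) hi <- min(hi, g[i] + eps)
          else if (s[i] == 5L) lo <- max(lo, g[i] - eps)
          else { lo <- max(lo, g[i] - eps); hi <- min(hi, g[i] + eps) }
        }
        if (lo > hi + tol) ok <- FALSE else mu <- (lo + hi) / 2
      } else if (ok) {
        for (i in seq_len(n)) {
          bad <- (s[i] == 1L && g[i] + eps - mu > tol) ||
                 (s[i] == 5L && g[i] - eps - mu < -tol) ||
                 (s[i] == 3L && abs(g[i] - mu) > eps + tol)
          if (bad) { ok <- FALSE; break }
        }
      }
      if (ok) {
        obj <- -0.5 * sum(b * (K %*% b)) + sum(y * b) - eps * sum(abs(b))
        if (obj > bestobj + 1e-12) {
          bestobj <- obj
          best <- list(w = as.vector(t(X) %*% b), b = mu, obj = obj)
        }
      }
    }
    i <- 1L
    while (i <= n && states[i] == 5L) { states[i] <- 1L; i <- i + 1L }
    if (i > n) break
    states[i] <- states[i] + 1L
  }
  best
}

# literal BH step-up: q_(k) = min_{j >= k} m * p_(j) / j, capped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) q[k] <- min(1, min(m * ps[k:m] / (k:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# double-gamma response evaluated on the sample grid (independent of the
# package's kernel code)
double_gamma_grid <- function(sampling_rate, peak, upeak, ratio, disp, span) {
  t <- seq(0, span, by = 1 / sampling_rate)
  g <- function(tt, p) ifelse(tt > 0, (tt / p)^(p / disp) * exp(-(tt - p) / disp), 0)
  g(t, peak) - ratio * g(t, upeak)
}

# noise specification used for the null-calibration studies: a single
# AR(1) component (geometric decay, so dependence dies within the block
# length) plus white noise
ar1_noise_spec <- function(phi = 0.9, white_sd = 0.4) {
  noise_spec(cardiac = c(1.2, 0), respiratory = c(0.3, 0),
             mayer = c(0.1, 0), vasomotion = c(0.04, 0),
             drift_amplitude = 1, drift_ar = phi, white_sd = white_sd)
}

# small coupled-dyad config: identity gain on the given student channels
coupled_config <- function(channels, gain = 1, duration = 900, seed = 1,
                           snr = 1, ...) {
  G <- matrix(0, 18, 18)
  for (j in channels) G[j, j] <- gain
  sim_config(duration = duration, coupling_gain = G, student_snr = snr,
             seed = seed, ...)
}
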