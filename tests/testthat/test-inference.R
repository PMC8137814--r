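test_that("Spearman correlation matches the rank formula and its invariances", {
  x <- c(2, 5, 9, 11)
  expect_equal(spearman_rho(x, x), 1.0)
  expect_equal(spearman_rho(x, rev(x)), -1.0)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 2
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  r0 <- spearman_rho(a, b)
  expect_equal(spearman_rho(exp(a), b), r0)          # strictly increasing maps
  expect_equal(spearman_rho(a, qcauchy(pnorm(b))), r0)
  expect_error(spearman_rho(a, rep(1, 100)), "constant")
  expect_error(spearman_rho(a, b[1:50]), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("block lag is the first near-zero ACF crossing, median-aggregated", {
  set.seed(2)
  n <- 7000
  white <- matrix(rnorm(n * 3), n, 3)
  expect_equal(find_block_lag(white, max_lag = 100)$lag, 1L)

  # AR(1) phi = 0.9: analytic ACF 0.9^k <= 0.05 first at k = 29
  ar <- replicate(4, as.vector(arima.sim(list(ar = 0.9), n)))
  lag <- find_block_lag(ar, threshold = 0.05, max_lag = 200)
  expect_true(abs(lag$lag - 29) <= 6)

  # mixed decorrelation times: aggregate = ceiling(median(per-channel))
  mix <- cbind(as.vector(arima.sim(list(ar = 0.75), n)),   # ~ lag 11
               as.vector(arima.sim(list(ar = 0.9), n)))    # ~ lag 29
  lmix <- find_block_lag(mix, max_lag = 200)
  expect_equal(lmix$lag, as.integer(ceiling(median(lmix$per_channel))))
  expect_equal(length(lmix$per_channel), 2L)

  slow <- matrix(cumsum(rnorm(3000)), ncol = 1)
  expect_error(find_block_lag(slow, max_lag = 50), "increase max_lag")
  expect_error(find_block_lag(white[1:100, ], max_lag = 100), "exceed")
})

test_that("block shuffle preserves samples and inter-channel structure", {
  set.seed(3)
  n <- 7000
  x <- matrix(rnorm(n * 2), n, 2)
  x[, 2] <- x[, 1] + 1                      # locked cross-channel relation
  sh <- block_shuffle(x, lag = 35, seed = 9)
  expect_equal(nrow(sh), 7000)              # 200 blocks of 35
  expect_equal(length(attr(sh, "permutation")), 200L)
  expect_equal(sort(sh[, 1]), sort(x[, 1])) # multiset preserved
  expect_equal(sh[, 2], sh[, 1] + 1)        # same permutation both columns

  # remainder samples are dropped when lag does not divide n
  sh2 <- block_shuffle(x, lag = 33, seed = 1)
  expect_equal(nrow(sh2), (7000 %/% 33) * 33)

  # single block: identity
  expect_equal(block_shuffle(x, lag = n, seed = 1), x, ignore_attr = TRUE)
  expect_error(block_shuffle(x, lag = n + 1), "exceeds")
  expect_error(block_shuffle(x, lag = 0), ">= 1")

  # seeded determinism
  expect_identical(block_shuffle(x, 35, seed = 4), block_shuffle(x, 35, seed = 4))
})

test_that("bootstrap p-value follows the literal ratio rule", {
  null <- c(seq(0.5, 0.9, length.out = 12), seq(-0.9, 0.4, length.out = 988))
  expect_equal(bootstrap_pvalue(0.45, null), 12 / 1000)
  expect_equal(bootstrap_pvalue(1.0, null), 0.0)
  expect_equal(bootstrap_pvalue(1.0, null, corrected = TRUE), 1 / 1001)
  expect_equal(bootstrap_pvalue(-1.0, null), 1.0)
  expect_error(bootstrap_pvalue(0.5, numeric(0)), "empty")
})

test_that("BH adjustment matches a brute-force step-up and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_equal(fdr_adjust(0.123), 0.123)
  set.seed(4)
  for (i in 1:5) {
    p <- runif(sample(3:25, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bh_stepup_oracle(p))
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the bootstrap null is seed-deterministic and centred for null dyads", {
  cfg <- sim_config(duration = 240, seed = 51, n_latent_events = 0L,
                    noise = ar1_noise_spec(0.9))
  d <- generate_dyad(cfg)
  n1 <- bootstrap_null(d, family = "OLS", response_channel = 4, B = 100,
                       seed = 77, max_lag = 200)
  n2 <- bootstrap_null(d, family = "OLS", response_channel = 4, B = 100,
                       seed = 77, max_lag = 200)
  expect_identical(n1$coefficients, n2$coefficients)
  expect_equal(length(n1$coefficients), 100)
  expect_equal(n1$n_blocks, nrow(d$teacher) %/% n1$lag)
  # for an uncoupled dyad the null is centred near zero
  se <- sd(n1$coefficients) / sqrt(100)
  expect_lt(abs(mean(n1$coefficients)), 3 * se + 0.02)
  expect_error(bootstrap_null(d, B = 50), "at least 100")
})

test_that("dyad evaluation produces a coherent channel x family table", {
  cfg <- coupled_config(channels = c(9, 10), gain = 1.2, duration = 240,
                        seed = 61, noise = ar1_noise_spec(0.9))
  d <- generate_dyad(cfg, id = "t1")
  fit <- fit_coupling(d, families = c("SVR", "OLS"))
  ev <- evaluate_coupling(fit, B = 100, max_lag = 200, seed = 5,
                          channels = c(1, 9, 10))
  r <- ev$results
  expect_equal(nrow(r), 6)                       # 3 channels x 2 families
  expect_setequal(names(r), c("dyad", "channel", "region", "family", "rho",
                              "p", "q", "sig_uncorrected", "sig_fdr"))
  expect_true(all(r$rho >= -1 & r$rho <= 1))
  expect_true(all(r$p >= 0 & r$p <= 1))
  expect_true(all(r$q >= r$p - 1e-12))           # BH never decreases p
  expect_true(all(r$sig_fdr <= r$sig_uncorrected))  # corrected is a subset
  expect_equal(unique(r$dyad), "t1")
  expect_equal(r$region[r$channel == 1][1], "PFC")
  expect_equal(r$region[r$channel == 9][1], "TPJ")

  # evaluation is deterministic under a fixed seed
  ev2 <- evaluate_coupling(fit, B = 100, max_lag = 200, seed = 5,
                           channels = c(1, 9, 10))
  expect_identical(ev$results, ev2$results)
})

test_that("an empty model grid evaluates to an empty table with a warning", {
  d <- generate_dyad(sim_config(duration = 90, seed = 71))
  fit <- fit_coupling(d, families = "OLS",
                      exclude_channels = 1:18)
  expect_warning(ev <- evaluate_coupling(fit, B = 100, max_lag = 150),
                 "no fitted channels")
  expect_equal(nrow(ev$results), 0)
})
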