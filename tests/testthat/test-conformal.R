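# Inductive conformal regression: scores, quantile rule, intervals,
# validity/efficiency, calibration curves and the coverage guarantee.

test_that("nonconformity scores follow the normalized-residual definition", {
  expect_equal(nonconformity(5, 5, 1, beta = 0.01), 0)
  expect_equal(nonconformity(1, 0, 0.9, beta = 0.1), 1)
  a1 <- nonconformity(2, 0, 0.4, beta = 0.1)
  a2 <- nonconformity(2, 0, 0.9, beta = 0.1)
  expect_equal(a1, 2 * a2) # doubling (spread+beta) halves the score
  expect_error(nonconformity(1, 0, 1, beta = 0), "positive")
  expect_equal(nonconformity(1, 0, 0.5, beta = 0.01, scaler = "exponential"),
               1 / exp(0.5))
})

test_that("the calibration quantile follows k = ceil((1-eps)(n+1))", {
  expect_equal(calibrate(1:19, 0.05), 19)   # k = ceil(0.95*20) = 19
  expect_equal(calibrate(5, 0.05), Inf)     # n_cal = 1 -> k = 2 > 1
  expect_equal(calibrate(c(3, 1, 2), 0.5), 2)
  expect_error(calibrate(numeric(0), 0.05), "empty")
})

test_that("calibrate matches the exhaustive counting oracle", {
  # oracle: smallest k whose guaranteed coverage k/(n+1) reaches 1-eps,
  # found by linear scan rather than ceiling arithmetic
  oracle <- function(alphas, eps) {
    a <- sort(alphas)
    n <- length(a)
    for (k in seq_len(n)) {
      if (k / (n + 1) >= 1 - eps) return(a[k])
    }
    Inf
  }
  withr::with_seed(42, {
    for (n in c(1:10, 25, 50)) {
      alphas <- runif(n, 0, 5)
      for (eps in seq(0.01, 0.5, by = 0.01)) {
        expect_identical(calibrate(alphas, eps), oracle(alphas, eps))
      }
    }
  })
})

test_that("intervals scale with alpha*, spread and confidence", {
  cal <- conformal_calibrator(y = c(rep(0, 19)), y_hat = rep(2, 19),
                              spread = rep(0.99, 19), beta = 0.01)
  # all scores = 2/1 = 2 -> alpha* = 2 at eps = 0.05 (k = 19)
  iv <- predict_interval(y_hat = 0, spread = 0.49, cal, epsilon = 0.05)
  expect_equal(iv$upper - iv$lower, 2 * 2 * 0.5) # 2*alpha*(spread+beta)
  expect_equal(iv$confidence, 0.95)
  # monotone in spread
  iv2 <- predict_interval(0, 0.8, cal, 0.05)
  expect_gt(iv2$upper - iv2$lower, iv$upper - iv$lower)
})

test_that("intervals are nested across confidence levels", {
  withr::with_seed(7, {
    y <- rnorm(80); yh <- y + rnorm(80, 0, 0.5); sp <- runif(80, 0, 1)
    cal <- conformal_calibrator(y[1:40], yh[1:40], sp[1:40])
    for (i in 41:60) {
      prev <- NULL
      for (eps in c(0.32, 0.2, 0.1, 0.05)) {
        iv <- predict_interval(yh[i], sp[i], cal, eps)
        if (!is.null(prev)) {
          # eps decreasing -> intervals widen: previous (higher-eps)
          # interval is contained in the current one
          expect_gte(prev$lower, iv$lower - 1e-12)
          expect_lte(prev$upper, iv$upper + 1e-12)
        }
        prev <- iv
      }
    }
  })
})

test_that("validity counts interval hits", {
  iv <- data.frame(lower = c(0, 0, 0, 0), upper = c(2, 2, 2, 2))
  expect_equal(validity(iv, c(1, 1, 1, 1)), 1)
  expect_equal(validity(iv, c(1, 1, 3, 3)), 0.5)
  expect_error(validity(iv, 1:3), "mismatch")
})

test_that("efficiency summarizes widths and flags unbounded intervals", {
  iv <- data.frame(lower = c(0, 0, 0), upper = c(2, 2, 2))
  e <- efficiency(iv)
  expect_equal(e$median, 2)
  expect_equal(e$q3 - e$q1, 0)
  iv2 <- data.frame(lower = c(0, 0, -Inf), upper = c(1, 3, Inf))
  e2 <- efficiency(iv2)
  expect_equal(e2$n_unbounded, 1L)
  expect_equal(e2$median, 2)
  # constant-spread degenerate model: all widths 2*alpha*beta
  cal <- conformal_calibrator(y = 1:19, y_hat = rep(0, 19),
                              spread = rep(0, 19), beta = 0.5)
  iv3 <- predict_interval(rep(0, 5), rep(0, 5), cal, 0.05)
  astar <- calibrate(cal, 0.05)
  expect_equal(unique(iv3$upper - iv3$lower), 2 * astar * 0.5)
})

test_that("calibration curves are monotone and saturate at tiny epsilon", {
  withr::with_seed(11, {
    y <- rnorm(500); yh <- y + rnorm(500, 0, 0.3); sp <- runif(500, 0, 0.5)
    cal <- conformal_calibrator(y[1:100], yh[1:100], sp[1:100])
    cc <- calibration_curve(cal, yh[101:500], sp[101:500], y[101:500],
                            epsilon_grid = c(0.001, 0.05, 0.1, 0.2, 0.4))
    expect_true(all(diff(cc$observed_error) >= -1e-12))
    # eps = 0.001 with 100 calibration scores -> k > n -> unbounded -> 0 error
    expect_equal(cc$observed_error[1], 0)
  })
})

test_that("split-conformal coverage holds marginally on exchangeable data", {
  # direct simulation of an uncertainty-aware predictor, no model fit:
  # heteroscedastic residuals with informative spread
  for (eps in c(0.05, 0.1, 0.2, 0.32)) {
    cov <- vapply(1:20, function(seed) {
      withr::with_seed(seed * 31L + 1L, {
        n_cal <- 200; n_test <- 400
        sp <- runif(n_cal + n_test, 0.1, 1)
        resid <- rnorm(n_cal + n_test, 0, sp)
        cal <- conformal_calibrator(resid[1:n_cal], rep(0, n_cal), sp[1:n_cal])
        iv <- predict_interval(rep(0, n_test), sp[n_cal + 1:n_test], cal, eps)
        validity(iv, resid[n_cal + 1:n_test])
      })
    }, numeric(1))
    se <- sqrt(eps * (1 - eps) / (20 * 400))
    expect_gte(mean(cov), 1 - eps - 3 * se)
  }
})

test_that("spread normalization narrows intervals at matched coverage", {
  # informative spread: normalized lambda beats a constant lambda
  wins <- 0L
  for (seed in 1:5) {
    withr::with_seed(seed * 17L, {
      n_cal <- 500; n_test <- 1000
      sp <- runif(n_cal + n_test, 0.05, 1.5)
      resid <- rnorm(n_cal + n_test, 0, sp)
      cal_norm <- conformal_calibrator(resid[1:n_cal], rep(0, n_cal),
                                       sp[1:n_cal])
      cal_const <- conformal_calibrator(resid[1:n_cal], rep(0, n_cal),
                                        rep(0, n_cal), beta = 1)
      ivn <- predict_interval(rep(0, n_test), sp[n_cal + 1:n_test], cal_norm,
                              0.1)
      ivc <- predict_interval(rep(0, n_test), rep(0, n_test), cal_const, 0.1)
      covn <- validity(ivn, resid[n_cal + 1:n_test])
      covc <- validity(ivc, resid[n_cal + 1:n_test])
      if (mean(ivn$upper - ivn$lower) <= mean(ivc$upper - ivc$lower) &&
          abs(covn - covc) < 0.05) {
        wins <- wins + 1L
      }
    })
  }
  expect_gte(wins, 4L)
})
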