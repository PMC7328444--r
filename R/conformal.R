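# Inductive (split) conformal regression with spread-normalized
# nonconformity: alpha = |y - y_hat| / lambda(spread), lambda = spread +
# beta (or exp(spread)). The calibration-set quantile of the alphas maps a
# confidence level to a per-instance interval half-width multiplier.

.lambda_of <- function(spread, beta, scaler) {
  switch(scaler,
         additive = spread + beta,
         exponential = exp(spread),
         stop("unknown spread scaler: ", scaler))
}

#' Nonconformity scores
#'
#' alpha = |y - y_hat| / (spread + beta) (additive scaler) or
#' |y - y_hat| / exp(spread) (exponential scaler).
#'
#' @param y true labels.
#' @param y_hat predicted means.
#' @param spread nonnegative per-instance spread.
#' @param beta smoothing constant (> 0) guarding degenerate spreads.
#' @param scaler `"additive"` or `"exponential"`.
#' @return nonconformity score vector.
#' @export
nonconformity <- function(y, y_hat, spread, beta = 0.01,
                          scaler = c("additive", "exponential")) {
  scaler <- match.arg(scaler)
  if (beta <= 0) stop("beta must be positive")
  stopifnot(all(spread >= 0), length(y) == length(y_hat),
            length(y) == length(spread))
  abs(y - y_hat) / .lambda_of(spread, beta, scaler)
}

#' Build a conformal calibrator from calibration-set scores
#'
#' @param y,y_hat,spread calibration-set labels, predictions and spreads.
#' @param beta smoothing constant.
#' @param scaler spread scaler, as in [nonconformity()].
#' @return a `pcm_conformal` calibrator holding the sorted scores.
#' @export
conformal_calibrator <- function(y, y_hat, spread, beta = 0.01,
                                 scaler = c("additive", "exponential")) {
  scaler <- match.arg(scaler)
  alphas <- sort(nonconformity(y, y_hat, spread, beta, scaler))
  structure(list(alphas = alphas, beta = beta, scaler = scaler,
                 n_cal = length(alphas)),
            class = "pcm_conformal")
}

#' Calibration quantile for an error level
#'
#' alpha* is the k-th smallest calibration score with
#' k = ceiling((1 - epsilon) * (n_cal + 1)); when k exceeds n_cal the
#' interval is unbounded (`Inf`).
#'
#' @param alphas sorted (or unsorted) nonconformity scores, or a
#'   `pcm_conformal` calibrator.
#' @param epsilon error level in (0, 1); confidence = 1 - epsilon.
#' @return the half-width multiplier alpha* (possibly `Inf`).
#' @export
calibrate <- function(alphas, epsilon) {
  if (inherits(alphas, "pcm_conformal")) alphas <- alphas$alphas
  if (length(alphas) == 0) stop("empty calibration set")
  stopifnot(epsilon > 0, epsilon < 1)
  a <- sort(alphas)
  n <- length(a)
  # epsilon guard: (1-eps)*(n+1) can land a hair above an integer in
  # floating point (e.g. 0.57*51), which would wrongly bump k
  k <- ceiling((1 - epsilon) * (n + 1) - 1e-9)
  if (k > n) Inf else a[k]
}

#' Conformal prediction intervals
#'
#' `[y_hat - alpha* lambda, y_hat + alpha* lambda]` at confidence
#' 1 - epsilon, with lambda the calibrator's spread scaler.
#'
#' @param y_hat predicted means.
#' @param spread per-instance spreads.
#' @param calibrator a [conformal_calibrator()].
#' @param epsilon error level.
#' @return data frame with `lower`, `upper`, `confidence` (class
#'   `pcm_intervals`).
#' @export
predict_interval <- function(y_hat, spread, calibrator, epsilon = 0.05) {
  stopifnot(inherits(calibrator, "pcm_conformal"),
            length(y_hat) == length(spread))
  astar <- calibrate(calibrator, epsilon)
  half <- astar * .lambda_of(spread, calibrator$beta, calibrator$scaler)
  out <- data.frame(lower = y_hat - half, upper = y_hat + half,
                    confidence = 1 - epsilon)
  class(out) <- c("pcm_intervals", class(out))
  out
}

#' Empirical validity (coverage) of prediction intervals
#'
#' @param intervals a [predict_interval()] result.
#' @param y_true true labels.
#' @return fraction of instances with lower <= y <= upper.
#' @export
validity <- function(intervals, y_true) {
  if (nrow(intervals) != length(y_true)) stop("length mismatch")
  mean(intervals$lower <= y_true & y_true <= intervals$upper)
}

#' Efficiency (interval width) summary
#'
#' Unbounded intervals are flagged and excluded from the summary, with
#' their count reported.
#'
#' @param intervals a [predict_interval()] result.
#' @return list with `widths`, `median`, `q1`, `q3`, `n_unbounded`.
#' @export
efficiency <- function(intervals) {
  stopifnot(nrow(intervals) > 0)
  w <- intervals$upper - intervals$lower
  unbounded <- !is.finite(w)
  wb <- w[!unbounded]
  if (length(wb) == 0) stop("all intervals unbounded; no width summary")
  q <- stats::quantile(wb, c(0.25, 0.5, 0.75), names = FALSE)
  list(widths = w, median = q[2], q1 = q[1], q3 = q[3],
       n_unbounded = sum(unbounded))
}

#' Calibration curve: theoretical vs observed error rates
#'
#' @param calibrator a [conformal_calibrator()].
#' @param y_hat,spread,y_true test-set predictions, spreads and labels.
#' @param epsilon_grid error levels to evaluate.
#' @return data frame with `epsilon`, `observed_error`, `validity`.
#' @export
calibration_curve <- function(calibrator, y_hat, spread, y_true,
                              epsilon_grid = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(all(epsilon_grid > 0), all(epsilon_grid < 1))
  obs <- vapply(epsilon_grid, function(eps) {
    iv <- predict_interval(y_hat, spread, calibrator, eps)
    validity(iv, y_true)
  }, numeric(1))
  data.frame(epsilon = epsilon_grid, observed_error = 1 - obs,
             validity = obs)
}
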