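## order-statistic index for a cumulative level: the bracket rule
## j = [level * B] read as round-to-nearest, clamped to [1, B]
order_index <- function(level, B) {
  pmin(pmax(round(level * B), 1L), B)
}

ci_row <- function(parameter, method, level, estimate, se = NA_real_,
                   lower, upper, z0 = NA_real_, a = NA_real_,
                   alpha1 = NA_real_, alpha2 = NA_real_) {
  data.frame(parameter = parameter, method = method, level = level,
             estimate = estimate, se = se, lower = lower, upper = upper,
             z0 = z0, a = a, alpha1 = alpha1, alpha2 = alpha2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentile bootstrap confidence interval
#'
#' The interval between the `alpha/2` and `1 - alpha/2` order statistics of
#' the bootstrap replicates: with the replicates sorted from lowest to
#' highest, the lower limit is the j-th and the upper limit the k-th value,
#' `j = round(B * alpha/2)` and `k = round(B * (1 - alpha/2))`, both clamped
#' to `[1, B]`.  With `B = 1000` and `alpha = 0.05` these are the 25th and
#' 975th order statistics.
#'
#' @param dist A [bootstrap_distribution()].
#' @param parameter Parameter label(s), or `NULL` for all.
#' @param alpha Significance level (0.05 for a 95% interval).
#' @return Data frame with one row per parameter: `parameter`, `method`,
#'   `level`, `estimate`, `se`, `lower`, `upper` (diagnostic columns `NA`).
#' @export
percentile_ci <- function(dist, parameter = NULL, alpha = 0.05) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  check_alpha(alpha, dist$B)
  est <- pick_columns(dist, parameter)
  j <- order_index(alpha / 2, dist$B)
  k <- order_index(1 - alpha / 2, dist$B)
  srt <- apply(est, 2, sort)
  ci_row(colnames(est), "percentile", 1 - alpha,
         dist$original[colnames(est)], apply(est, 2, sd),
         srt[j, ], srt[k, ])
}

check_alpha <- function(alpha, B) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (B * alpha / 2 < 1)
    stop("too few bootstrap resamples: need B * alpha/2 >= 1 (B = ", B,
         ", alpha = ", alpha, ")")
}

#' Bias-correction factor for the BCa interval
#'
#' `z0 = qnorm(c / B)` where `c` counts bootstrap replicates strictly below
#' the original estimate (ties are not counted).  The count is clamped to
#' `[0.5, B - 0.5]` before division so that degenerate counts of 0 or B
#' give a finite value.
#'
#' @inheritParams percentile_ci
#' @return Named numeric vector of bias-correction factors.
#' @export
bias_correction <- function(dist, parameter = NULL) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  est <- pick_columns(dist, parameter)
  orig <- dist$original[colnames(est)]
  cnt <- colSums(sweep(est, 2, orig, "<"))
  cnt <- pmin(pmax(cnt, 0.5), dist$B - 0.5)
  setNames(qnorm(cnt / dist$B), colnames(est))
}

#' Acceleration factor from a jackknife distribution
#'
#' `a = sum(d^3) / (6 * (sum(d^2))^(3/2))` with `d_i` the deviation of the
#' jackknife column mean from the i-th leave-one-out estimate.  When all
#' leave-one-out estimates are equal the factor is defined as 0.
#'
#' @param jack A [jackknife_distribution()].
#' @param parameter Parameter label(s), or `NULL` for all.
#' @return Named numeric vector of acceleration factors.
#' @export
acceleration <- function(jack, parameter = NULL) {
  stopifnot(inherits(jack, "jackknife_distribution"))
  est <- if (is.null(parameter)) jack$estimates else {
    missing <- setdiff(parameter, colnames(jack$estimates))
    if (length(missing))
      stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    jack$estimates[, parameter, drop = FALSE]
  }
  d <- sweep(-est, 2, colMeans(est), "+")   # theta_bar - theta_(-i)
  num <- colSums(d^3)
  den <- 6 * colSums(d^2)^1.5
  a <- ifelse(den == 0, 0, num / den)
  setNames(a, colnames(est))
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' A percentile-type interval whose quantile levels are adjusted for the
#' median bias and the skewness of the bootstrap distribution:
#' `alpha1 = pnorm(z0 + (z0 + z_lo) / (1 - a (z0 + z_lo)))` with
#' `z_lo = qnorm(alpha/2)`, and `alpha2` analogously with
#' `z_hi = qnorm(1 - alpha/2)`.  The interval endpoints are the order
#' statistics at ranks `round(alpha1 * B)` and `round(alpha2 * B)`
#' (clamped to `[1, B]`).  With `z0 = 0` and `a = 0` the interval reduces
#' exactly to the percentile interval.
#'
#' @inheritParams percentile_ci
#' @param jack A [jackknife_distribution()] for the same parameters.
#' @return Data frame as [percentile_ci()], with the diagnostic columns
#'   `z0`, `a`, `alpha1`, `alpha2` populated.
#' @export
bca_ci <- function(dist, jack, parameter = NULL, alpha = 0.05) {
  stopifnot(inherits(dist, "bootstrap_distribution"),
            inherits(jack, "jackknife_distribution"))
  check_alpha(alpha, dist$B)
  est <- pick_columns(dist, parameter)
  pars <- colnames(est)
  z0 <- bias_correction(dist, pars)
  a <- acceleration(jack, pars)
  z_lo <- qnorm(alpha / 2)
  z_hi <- qnorm(1 - alpha / 2)
  den1 <- 1 - a * (z0 + z_lo)
  den2 <- 1 - a * (z0 + z_hi)
  if (any(den1 == 0) || any(den2 == 0))
    stop("BCa adjustment undefined: 1 - a*(z0 + z) = 0 for ",
         paste(pars[den1 == 0 | den2 == 0], collapse = ", "))
  alpha1 <- pnorm(z0 + (z0 + z_lo) / den1)
  alpha2 <- pnorm(z0 + (z0 + z_hi) / den2)
  srt <- apply(est, 2, sort)
  lower <- srt[cbind(order_index(alpha1, dist$B), seq_along(pars))]
  upper <- srt[cbind(order_index(alpha2, dist$B), seq_along(pars))]
  ci_row(pars, "bca", 1 - alpha, dist$original[pars], apply(est, 2, sd),
         pmin(lower, upper), pmax(lower, upper), z0, a, alpha1, alpha2)
}

#' Bootstrap Student's t confidence interval
#'
#' Symmetric interval about the estimate assuming the studentized estimate
#' is approximately t-distributed with `n - 1` degrees of freedom, `n` the
#' original sample size: estimate plus/minus the t quantile times the
#' bootstrap standard error.
#'
#' @param estimate Named numeric vector of estimates.
#' @param se Bootstrap standard error(s) (divisor B - 1), `>= 0`.
#' @param n Original sample size (>= 2).
#' @param alpha Significance level.
#' @return Data frame as [percentile_ci()] with `method = "student_t"`.
#' @export
student_t_ci <- function(estimate, se, n, alpha = 0.05) {
  if (n < 2) stop("`n` must be at least 2")
  if (any(se < 0)) stop("`se` must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  tq <- qt(1 - alpha / 2, df = n - 1)
  nm <- if (is.null(names(estimate))) rep(NA_character_, length(estimate))
        else names(estimate)
  ci_row(nm, "student_t", 1 - alpha, unname(estimate), se,
         unname(estimate) - tq * se, unname(estimate) + tq * se)
}

#' All bootstrap confidence intervals for a GSCA fit
#'
#' Convenience wrapper producing percentile, BCa, and Student's t intervals
#' (or any subset) for every free parameter from one shared bootstrap pass
#' and, when BCa is requested, one jackknife pass.
#'
#' @param dist A [bootstrap_distribution()].
#' @param jack A [jackknife_distribution()]; required for `"bca"`.
#' @param methods Subset of `c("percentile", "bca", "student_t")`.
#' @param alpha Significance level.
#' @return Data frame with one row per (parameter, method).
#' @export
gsca_ci <- function(dist, jack = NULL,
                    methods = c("percentile", "bca", "student_t"),
                    alpha = 0.05) {
  methods <- match.arg(methods, c("percentile", "bca", "student_t"),
                       several.ok = TRUE)
  out <- list()
  if ("percentile" %in% methods)
    out$percentile <- percentile_ci(dist, alpha = alpha)
  if ("bca" %in% methods) {
    if (is.null(jack)) stop("BCa intervals require a jackknife distribution")
    out$bca <- bca_ci(dist, jack, alpha = alpha)
  }
  if ("student_t" %in% methods)
    out$student_t <- student_t_ci(dist$original,
                                  bootstrap_se(dist), dist$n, alpha)
  do.call(rbind, unname(out))
}
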