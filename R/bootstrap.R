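#' Draw a bootstrap resampling index vector
#'
#' `n` indices drawn uniformly with replacement from `1..n`, deterministic
#' for a given seed.  The caller's RNG state is untouched.
#'
#' @param n Original sample size (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
resample_indices <- function(n, seed) {
  if (n < 2) stop("`n` must be at least 2")
  with_seed(seed, sample.int(n, n, replace = TRUE))
}

#' Construct a bootstrap distribution object
#'
#' Container for `B` aligned re-estimates of `K` parameters together with
#' the original estimates.  [gsca_bootstrap()] builds one by refitting a
#' GSCA model on resampled data; the constructor is exported so that the
#' interval methods can be applied to any statistic (e.g. a sample mean)
#' whose replicates are computed elsewhere.
#'
#' @param estimates B x K numeric matrix, one column per parameter, columns
#'   named.
#' @param original Named numeric vector of the K original estimates.
#' @param n Original sample size.
#' @param n_failed Number of resamples that were discarded and redrawn.
#' @return Object of class `bootstrap_distribution`.
#' @export
bootstrap_distribution <- function(estimates, original, n,
                                   n_failed = 0L) {
  estimates <- as.matrix(estimates)
  if (is.null(colnames(estimates))) colnames(estimates) <- names(original)
  if (nrow(estimates) < 2) stop("need at least B = 2 bootstrap replicates")
  if (!identical(colnames(estimates), names(original)))
    stop("column labels of `estimates` must match names of `original`")
  if (any(!is.finite(estimates))) stop("non-finite bootstrap estimates")
  structure(list(estimates = estimates, original = original,
                 B = nrow(estimates), n = n, n_failed = as.integer(n_failed)),
            class = "bootstrap_distribution")
}

#' Construct a jackknife distribution object
#'
#' @param estimates n x K numeric matrix of leave-one-out estimates, row i
#'   from the sample with case i removed; columns named.
#' @param original Optional named original estimate vector (for label
#'   checking).
#' @return Object of class `jackknife_distribution` with `estimates` and
#'   `means` (the column averages).
#' @export
jackknife_distribution <- function(estimates, original = NULL) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 3) stop("jackknife needs n >= 3")
  if (!is.null(original) &&
      !identical(colnames(estimates), names(original)))
    stop("column labels must match the original parameter vector")
  structure(list(estimates = estimates, means = colMeans(estimates),
                 n = nrow(estimates)),
            class = "jackknife_distribution")
}

## one admissible GSCA refit of resampled rows, aligned to the original
refit_aligned <- function(raw, idx, model, original, tol, max_iter) {
  fit <- gsca_fit(raw[idx, , drop = FALSE], model,
                  init_weights = original$weights,
                  tol = tol, max_iter = max_iter)
  if (!fit$converged) stop_inadmissible("resample did not converge")
  sign_align(fit, original)
}

#' Bootstrap distribution of GSCA parameter estimates
#'
#' Draws `B` resamples of the rows of `data` with replacement,
#' re-standardizes each resample (the estimator's own preprocessing is part
#' of the resampled statistic), refits the GSCA model warm-started from the
#' original weights, aligns component signs to the original fit, and
#' collects the free loadings and path coefficients.  Inadmissible
#' resamples (a singular within-block subproblem, a constant column, or
#' non-convergence) are redrawn with a fresh seed increment and counted.
#'
#' @param data The original raw n x J data.
#' @param model A [gsca_model()].
#' @param fit The converged original [gsca_fit()].
#' @param B Number of bootstrap samples.
#' @param seed Integer seed.  The whole pass draws its resampling indices
#'   from one RNG stream seeded once, so two passes with different seeds
#'   have fully distinct resampling sequences.
#' @param tol,max_iter Passed to [gsca_fit()].
#' @return A [bootstrap_distribution()] with `B` rows.
#' @export
gsca_bootstrap <- function(data, model, fit, B = 1000, seed = 1,
                           tol = 1e-5, max_iter = 300) {
  stopifnot(inherits(fit, "gsca_fit"))
  if (!fit$converged) stop("original fit did not converge")
  raw <- as.matrix(data)
  if (!is.null(colnames(raw)) && all(model$indicators %in% colnames(raw)))
    raw <- raw[, model$indicators, drop = FALSE]
  n <- nrow(raw)
  if (n < 2) stop("`n` must be at least 2")
  K <- length(fit$parameters)
  est <- matrix(NA_real_, B, K, dimnames = list(NULL, names(fit$parameters)))
  n_failed <- 0L
  max_failed <- ceiling(0.10 * B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        rb <- tryCatch(
          refit_aligned(raw, idx, model, fit, tol, max_iter),
          gsca_inadmissible_error = function(e) NULL,
          error = function(e) NULL)
        if (!is.null(rb)) break
        # inadmissible: redraw fresh indices, keep the count
        n_failed <- n_failed + 1L
        if (n_failed > max_failed)
          stop("more than 10% of bootstrap resamples were inadmissible; ",
               "the data are too degenerate to bootstrap")
      }
      est[b, ] <- rb$parameters
    }
  })
  bootstrap_distribution(est, fit$parameters, n, n_failed)
}

#' Jackknife (leave-one-out) distribution of GSCA parameter estimates
#'
#' Performs `n` refits, the i-th on the data with row i removed and
#' re-standardized, each warm-started from and sign-aligned to the original
#' fit.  Used to estimate the BCa acceleration factor.
#'
#' @inheritParams gsca_bootstrap
#' @return A [jackknife_distribution()] with `n` rows.
#' @export
gsca_jackknife <- function(data, model, fit, tol = 1e-5, max_iter = 300) {
  stopifnot(inherits(fit, "gsca_fit"))
  if (!fit$converged) stop("original fit did not converge")
  raw <- as.matrix(data)
  if (!is.null(colnames(raw)) && all(model$indicators %in% colnames(raw)))
    raw <- raw[, model$indicators, drop = FALSE]
  n <- nrow(raw)
  if (n < 3) stop("jackknife needs n >= 3")
  K <- length(fit$parameters)
  est <- matrix(NA_real_, n, K, dimnames = list(NULL, names(fit$parameters)))
  for (i in seq_len(n)) {
    ri <- refit_aligned(raw, setdiff(seq_len(n), i), model, fit,
                        tol, max_iter)
    est[i, ] <- ri$parameters
  }
  jackknife_distribution(est, fit$parameters)
}

#' Bootstrap standard error
#'
#' Standard deviation (divisor B - 1) of the bootstrap replicates of one
#' parameter, or of every parameter when `parameter` is `NULL`.
#'
#' @param dist A [bootstrap_distribution()].
#' @param parameter Parameter label, or `NULL` for all.
#' @return Named numeric vector of standard errors.
#' @export
bootstrap_se <- function(dist, parameter = NULL) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  est <- pick_columns(dist, parameter)
  apply(est, 2, sd)
}

#' Critical ratio of an estimate
#'
#' The bootstrap t statistic: a parameter estimate divided by its bootstrap
#' standard error.
#'
#' @param estimate Numeric estimate(s).
#' @param se Positive standard error(s).
#' @return `estimate / se`.
#' @export
critical_ratio <- function(estimate, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  estimate / se
}

pick_columns <- function(dist, parameter) {
  if (is.null(parameter)) return(dist$estimates)
  missing <- setdiff(parameter, colnames(dist$estimates))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  dist$estimates[, parameter, drop = FALSE]
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat("Bootstrap distribution: B =", x$B, "replicates of",
      ncol(x$estimates), "parameters (n =", x$n,
      ", redrawn:", x$n_failed, ")\n")
  invisible(x)
}

#' @export
print.jackknife_distribution <- function(x, ...) {
  cat("Jackknife distribution:", x$n, "leave-one-out estimates of",
      ncol(x$estimates), "parameters\n")
  invisible(x)
}
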