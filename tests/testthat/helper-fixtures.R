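# Shared fixtures, built in code.

# one-block, two-indicator model
model_2ind <- function() gsca_model(list(eta1 = c("z1", "z2")), NULL)

# one-block, three-indicator model
model_3ind <- function() gsca_model(list(eta1 = c("z1", "z2", "z3")), NULL)

# two blocks with one structural path
model_2block <- function()
  gsca_model(list(eta1 = c("x1", "x2"), eta2 = c("y1", "y2")),
             paths = "eta1 -> eta2")

# n x 2 standardized matrix whose sample correlation (divisor n) is exactly r
exact_corr_pair <- function(r, n = 40, seed = 11) {
  stopifnot(abs(r) < 1)
  base <- with_fixed_seed(seed, matrix(rnorm(2 * n), n, 2))
  z1 <- gsca_standardize(base[, 1, drop = FALSE])[, 1]
  e <- base[, 2] - mean(base[, 2])
  e <- e - z1 * sum(e * z1) / sum(z1^2)        # orthogonal to z1
  e <- e / sqrt(mean(e^2))
  cbind(z1 = z1, z2 = r * z1 + sqrt(1 - r^2) * e)
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# brute-force percentile / BCa endpoints: sort and index by hand
brute_percentile <- function(reps, alpha) {
  B <- length(reps)
  srt <- sort(reps)
  j <- min(max(round(alpha / 2 * B), 1), B)
  k <- min(max(round((1 - alpha / 2) * B), 1), B)
  c(srt[j], srt[k])
}

brute_bca <- function(reps, original, jack, alpha) {
  B <- length(reps)
  cnt <- sum(reps < original)
  cnt <- min(max(cnt, 0.5), B - 0.5)
  z0 <- qnorm(cnt / B)
  d <- mean(jack) - jack
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  a1 <- pnorm(z0 + (z0 + qnorm(alpha / 2)) / (1 - a * (z0 + qnorm(alpha / 2))))
  a2 <- pnorm(z0 + (z0 + qnorm(1 - alpha / 2)) /
                (1 - a * (z0 + qnorm(1 - alpha / 2))))
  srt <- sort(reps)
  c(srt[min(max(round(a1 * B), 1), B)], srt[min(max(round(a2 * B), 1), B)])
}

# bootstrap distribution of the sample mean, vectorized; plus its jackknife
mean_bootstrap <- function(x, B, seed) {
  n <- length(x)
  reps <- with_fixed_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
    matrix(rowMeans(matrix(x[idx], B, n)), B, 1,
           dimnames = list(NULL, "mean"))
  })
  bootstrap_distribution(reps, c(mean = mean(x)), n)
}

mean_jackknife <- function(x) {
  n <- length(x)
  loo <- (n * mean(x) - x) / (n - 1)
  jackknife_distribution(matrix(loo, n, 1, dimnames = list(NULL, "mean")))
}
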