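make_dist <- function(reps, original = NULL, n = 50) {
  reps <- as.matrix(reps)
  colnames(reps) <- "p"
  if (is.null(original)) original <- c(p = mean(reps))
  bootstrap_distribution(reps, setNames(original, "p"), n)
}

test_that("percentile endpoints are the bracketed order statistics", {
  # worked example: B = 1000, alpha = 0.05 -> 25th and 975th order statistics
  reps <- with_fixed_seed(1, sample(1:1000))
  ci <- percentile_ci(make_dist(reps), alpha = 0.05)
  expect_equal(ci$lower, 25)
  expect_equal(ci$upper, 975)

  # enumerated small case: replicates 1..20 at alpha = 0.10 -> [1, 19]
  ci2 <- percentile_ci(make_dist(1:20), alpha = 0.10)
  expect_equal(c(ci2$lower, ci2$upper), c(1, 19))

  # degenerate distribution collapses to a point
  ci3 <- percentile_ci(make_dist(rep(3.5, 40)), alpha = 0.05)
  expect_equal(c(ci3$lower, ci3$upper), c(3.5, 3.5))

  expect_error(percentile_ci(make_dist(1:10), alpha = 0.05),
               "too few bootstrap resamples")
})

test_that("decreasing alpha never narrows the percentile interval", {
  reps <- with_fixed_seed(2, rnorm(400))
  alphas <- c(0.32, 0.2, 0.1, 0.05, 0.01)
  w <- vapply(alphas, function(a) {
    ci <- percentile_ci(make_dist(reps), alpha = a)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("bias correction counts strictly-below replicates with clamping", {
  reps <- 1:1000
  expect_equal(bias_correction(make_dist(reps, original = 500.5))[["p"]], 0)
  expect_equal(bias_correction(make_dist(reps, original = 975.5))[["p"]],
               qnorm(0.975), tolerance = 1e-10)
  # printed constant: qnorm(0.975) = 1.96 to two decimals
  expect_equal(round(qnorm(0.975), 2), 1.96)
  # no replicate below the original: clamped, finite
  z0 <- bias_correction(make_dist(reps, original = 0.5))[["p"]]
  expect_equal(z0, qnorm(0.5 / 1000))
  expect_true(is.finite(z0))
  # ties are not counted as below
  tied <- make_dist(c(rep(1, 10), rep(2, 10)), original = 1)
  expect_equal(bias_correction(tied)[["p"]], qnorm(0.5 / 20))
})

test_that("acceleration follows the jackknife skewness formula", {
  jd <- function(v) jackknife_distribution(matrix(v, ncol = 1,
                                                  dimnames = list(NULL, "p")))
  expect_equal(acceleration(jd(rep(2, 5)))[["p"]], 0)
  expect_equal(acceleration(jd(c(-1, 0, 1)))[["p"]], 0)
  expect_equal(acceleration(jd(c(0, 0, 3)))[["p"]], -6 / (6 * 6^1.5),
               tolerance = 1e-12)
})

test_that("BCa reduces to percentile when z0 = 0 and a = 0", {
  reps <- 1:20
  dist <- make_dist(reps, original = 10.5)   # half below -> z0 = 0
  jack <- jackknife_distribution(matrix(c(-1, 0, 1), 3, 1,
                                        dimnames = list(NULL, "p")))
  bca <- bca_ci(dist, jack, alpha = 0.10)
  pct <- percentile_ci(dist, alpha = 0.10)
  expect_equal(bca$z0, 0)
  expect_equal(bca$a, 0)
  expect_equal(bca$alpha1, 0.05, tolerance = 1e-12)
  expect_equal(bca$alpha2, 0.95, tolerance = 1e-12)
  expect_equal(c(bca$lower, bca$upper), c(pct$lower, pct$upper))
})

test_that("BCa adjusted levels match the analytic formula for z0 = qnorm(0.975)", {
  reps <- 1:1000
  dist <- make_dist(reps, original = 975.5)
  jack <- jackknife_distribution(matrix(c(-1, 0, 1), 3, 1,
                                        dimnames = list(NULL, "p")))
  bca <- bca_ci(dist, jack, alpha = 0.05)
  z0 <- qnorm(0.975)
  # with a = 0 the adjusted levels are Phi(2 z0 + z): the lower level
  # collapses back to Phi(z0) = 0.975, the upper to Phi(2 z0 + z_hi)
  expect_equal(bca$z0, z0, tolerance = 1e-10)
  expect_equal(bca$alpha1, pnorm(z0), tolerance = 1e-10)
  expect_equal(bca$alpha1, 0.975, tolerance = 1e-10)
  expect_equal(bca$alpha2, pnorm(2 * z0 + qnorm(0.975)), tolerance = 1e-10)
})

test_that("percentile and BCa endpoints match a brute-force oracle on small fixtures", {
  for (seed in 1:4) {
    reps <- with_fixed_seed(200 + seed, round(rnorm(20, 1, 2), 3))
    orig <- with_fixed_seed(300 + seed, rnorm(1, 1, 0.5))
    jack <- with_fixed_seed(400 + seed, rnorm(8, 1, 0.7))
    dist <- make_dist(reps, original = orig)
    jd <- jackknife_distribution(matrix(jack, ncol = 1,
                                        dimnames = list(NULL, "p")))
    for (alpha in c(0.10, 0.32)) {
      pct <- percentile_ci(dist, alpha = alpha)
      expect_equal(c(pct$lower, pct$upper), brute_percentile(reps, alpha))
      bca <- bca_ci(dist, jd, alpha = alpha)
      expect_equal(c(bca$lower, bca$upper),
                   brute_bca(reps, orig, jack, alpha))
    }
  }
})

test_that("Student's t intervals use df = n-1 and the bootstrap SE", {
  ci <- student_t_ci(c(p = 2), se = 0.5, n = 10, alpha = 0.05)
  expect_equal(c(ci$lower, ci$upper),
               c(2 - qt(0.975, 9) * 0.5, 2 + qt(0.975, 9) * 0.5))
  expect_equal(c(ci$lower, ci$upper), c(0.8689, 3.1311), tolerance = 1e-4)

  # zero SE collapses to the estimate
  ci0 <- student_t_ci(c(p = 1.2), se = 0, n = 25)
  expect_equal(c(ci0$lower, ci0$upper), c(1.2, 1.2))

  # large-df limit approaches the normal quantile
  ciN <- student_t_ci(c(p = 0), se = 1, n = 10001, alpha = 0.05)
  expect_equal(c(ciN$lower, ciN$upper), c(-1.9602, 1.9602), tolerance = 1e-4)
})

test_that("lower <= upper for every method on rough fixtures", {
  for (seed in 1:5) {
    reps <- with_fixed_seed(500 + seed, exp(rnorm(200)))
    dist <- make_dist(reps, original = with_fixed_seed(600 + seed,
                                                       exp(rnorm(1))))
    jack <- jackknife_distribution(
      matrix(with_fixed_seed(700 + seed, exp(rnorm(12))), ncol = 1,
             dimnames = list(NULL, "p")))
    out <- rbind(percentile_ci(dist, alpha = 0.05),
                 bca_ci(dist, jack, alpha = 0.05),
                 student_t_ci(dist$original, bootstrap_se(dist), dist$n))
    expect_true(all(out$lower <= out$upper))
  }
})

test_that("the combined interval table has one row per parameter and method", {
  pop <- gsca_population()
  raw <- generate_normal(pop, 50, seed = 41)
  fit <- gsca_fit(raw, pop$model)
  bd <- gsca_bootstrap(raw, pop$model, fit, B = 40, seed = 1)
  jk <- gsca_jackknife(raw, pop$model, fit)
  tab <- gsca_ci(bd, jk, alpha = 0.05)
  expect_equal(nrow(tab), 24 * 3)
  expect_equal(sort(unique(tab$method)),
               c("bca", "percentile", "student_t"))
  expect_true(all(tab$lower <= tab$upper))
  expect_error(gsca_ci(bd, NULL, methods = c("percentile", "bca")),
               "require a jackknife")
})
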