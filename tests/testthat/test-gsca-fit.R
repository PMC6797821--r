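test_that("criterion matches the closed-form residual for a 0.28-correlation block", {
  z <- exact_corr_pair(0.28)
  n <- nrow(z)
  m <- model_2ind()
  w <- matrix(c(1, 1), 2, 1)
  w <- w * sqrt(n / drop(crossprod(w, crossprod(z) %*% w)))
  f <- fit_criterion(z, m, weights = w,
                     loadings = matrix(c(0.8, 0.8), 1, 2),
                     paths = matrix(0, 1, 1))
  expect_equal(f, n * (2 - 2 * 0.8^2), tolerance = 1e-10)
})

test_that("criterion is zero for a saturated single-indicator model and never negative", {
  m <- gsca_model(list(eta = "z1"), NULL)
  z <- gsca_standardize(matrix(rnorm(30), ncol = 1,
                               dimnames = list(NULL, "z1")))
  f <- fit_criterion(z, m, weights = matrix(1, 1, 1),
                     loadings = matrix(1, 1, 1), paths = matrix(0, 1, 1))
  expect_equal(f, 0, tolerance = 1e-10)

  m2 <- model_2ind()
  z2 <- exact_corr_pair(0.4)
  for (l in list(c(0, 0), c(1, -1), c(0.5, 2))) {
    w <- matrix(c(1, 1), 2, 1)
    w <- w * sqrt(nrow(z2) / drop(crossprod(w, crossprod(z2) %*% w)))
    expect_gte(fit_criterion(z2, m2, w, matrix(l, 1, 2),
                             matrix(0, 1, 1)), 0)
  }
})

test_that("criterion validates masks and dimensions", {
  m <- model_2block()
  z <- gsca_standardize(matrix(rnorm(80), 20, 4))
  w <- m$weight_pattern * 0.5
  expect_error(fit_criterion(z[, 1:3], m, w, t(w), matrix(0, 2, 2)),
               "columns")
  bad_l <- t(w); bad_l[1, 3] <- 0.2   # loading outside own block
  expect_error(fit_criterion(z, m, w, bad_l, matrix(0, 2, 2)),
               "outside the loading pattern")
})

test_that("two-indicator block recovers the sqrt((1+r)/2) loading closed form", {
  z <- exact_corr_pair(0.28)
  fit <- gsca_fit(z, model_2ind(), tol = 1e-10)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.8, 0.8), tolerance = 1e-8)
  expect_equal(unname(fit$weights[1, 1]), unname(fit$weights[2, 1]),
               tolerance = 1e-8)
})

test_that("perfectly redundant indicators give equal weights and unit loadings", {
  z1 <- gsca_standardize(matrix(rnorm(25), ncol = 1))[, 1]
  z <- cbind(z1 = z1, z2 = z1)
  fit <- gsca_fit(z, model_2ind(), tol = 1e-10)
  expect_equal(unname(coef(fit)), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(fit$weights[1, 1]), unname(fit$weights[2, 1]),
               tolerance = 1e-8)
})

test_that("single-block solutions match a principal-component oracle", {
  for (seed in 1:5) {
    x <- with_fixed_seed(100 + seed, {
      base <- rnorm(40)
      cbind(z1 = base + rnorm(40, sd = 0.8),
            z2 = base + rnorm(40, sd = 0.6),
            z3 = -base + rnorm(40, sd = 1.2))
    })
    z <- gsca_standardize(x)
    n <- nrow(z)
    # oracle: loadings are correlations with the unit-variance first
    # principal component score
    R <- crossprod(z) / n
    e1 <- eigen(R, symmetric = TRUE)$vectors[, 1]
    score <- z %*% e1
    score <- score / sqrt(mean(score^2))
    oracle <- unname(drop(crossprod(z, score) / n))
    if (sum(oracle) < 0) oracle <- -oracle
    fit <- gsca_fit(z, model_3ind(), tol = 1e-12)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-6)
  }
})

test_that("the ALS fit sequence is non-increasing and component scores have unit variance", {
  pop <- gsca_population()
  raw <- generate_normal(pop, 80, seed = 17)
  fit <- gsca_fit(raw, pop$model)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 300)
  expect_true(all(diff(fit$fit_history) <= 1e-8))
  z <- gsca_standardize(raw)
  scores <- z %*% fit$weights
  expect_equal(unname(colMeans(scores^2)), rep(1, 6), tolerance = 1e-8)
  # masked entries exactly zero
  expect_true(all(fit$weights[!pop$model$weight_pattern] == 0))
  expect_true(all(fit$loadings[!pop$model$loading_pattern] == 0))
  expect_true(all(fit$paths[!pop$model$path_pattern] == 0))
})

test_that("negating a block's indicators reflects only that component", {
  pop <- gsca_population()
  raw <- generate_normal(pop, 60, seed = 23)
  f1 <- gsca_fit(raw, pop$model, tol = 1e-9)
  raw2 <- raw
  raw2[, 1:3] <- -raw2[, 1:3]
  f2 <- gsca_fit(raw2, pop$model, tol = 1e-9)
  # the fit and all loadings are unchanged (the sum-of-loadings convention
  # keeps every block's loadings positively oriented); the reflected
  # component's score changes sign, so its structural coefficients do too
  expect_equal(f1$fit, f2$fit, tolerance = 1e-6)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-6)
  flip <- f2$paths
  flip[1, ] <- -flip[1, ]; flip[, 1] <- -flip[, 1]
  expect_equal(f1$paths, flip, tolerance = 1e-6)
  # the weights themselves are unchanged: applied to the negated
  # indicators they produce the reflected component score
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
})

test_that("sign alignment flips flipped components and respects the zero tie-break", {
  pop <- gsca_population()
  raw <- generate_normal(pop, 60, seed = 29)
  fit <- gsca_fit(raw, pop$model)
  flipped <- fit
  for (p in c(2, 5)) {
    flipped$weights[, p] <- -flipped$weights[, p]
    flipped$loadings[p, ] <- -flipped$loadings[p, ]
    flipped$paths[p, ] <- -flipped$paths[p, ]
    flipped$paths[, p] <- -flipped$paths[, p]
  }
  aligned <- sign_align(flipped, fit)
  expect_equal(aligned$weights, fit$weights, tolerance = 1e-12)
  expect_equal(aligned$parameters, fit$parameters, tolerance = 1e-12)
  # aligning a result to itself is the identity
  expect_equal(sign_align(fit, fit)$parameters, fit$parameters)
  # orthogonal weights (inner product 0) leave the candidate unchanged
  ref <- fit
  ref$weights[, 1] <- 0
  expect_equal(sign_align(fit, ref)$parameters, fit$parameters)
})
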