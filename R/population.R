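## The built-in population path structure: four exogenous components
## (gamma1..gamma4) and two endogenous ones (gamma5, gamma6), six free path
## coefficients, three indicators per component.  The exogenous components
## are equicorrelated; the default correlation is the value at which the
## structural model's explained variances equal 0.168 (gamma5) and 0.383
## (gamma6).
default_path_table <- function() {
  data.frame(
    from = c("gamma1", "gamma2", "gamma1", "gamma2", "gamma3", "gamma5"),
    to   = c("gamma5", "gamma5", "gamma6", "gamma6", "gamma6", "gamma6"),
    value = c(-0.25, -0.2, -0.75, 0.55, 0.35, -0.15),
    stringsAsFactors = FALSE)
}

default_exo_rho <- 0.6551796

#' Construct the simulation population model
#'
#' Builds a six-component population model: four exogenous components with
#' an equicorrelated correlation matrix and two endogenous ones wired as
#' `gamma5 ~ gamma1 + gamma2` and `gamma6 ~ gamma1 + gamma2 + gamma3 +
#' gamma5`, with path coefficients (-0.25, -0.2, -0.75, 0.55, 0.35, -0.15).
#' Every component has three indicators with standardized loadings
#' `loadings` (default 0.7, 0.8, 0.9).  Structural residual variances are
#' chosen so every component has unit variance; at the default exogenous
#' correlation the explained variances are 0.168 for gamma5 and 0.383 for
#' gamma6.
#'
#' Two constructions of the implied indicator correlation matrix are
#' available.  The default, `sigma_mode = "composite"`, builds a composite
#' population: within each block the indicators are equicorrelated at the
#' (uniquely determined) correlation for which a unit-variance weighted
#' composite of the block reproduces `loadings` exactly as
#' indicator-composite covariances, and between-block covariances are
#' `loading_i * phi * loading_j`.  For loadings (0.7, 0.8, 0.9) the
#' within-block correlation is exactly 0.5 and the composite weights are
#' (0.2, 0.4, 0.6).  Under this construction a composite estimator such as
#' GSCA recovers the population loadings and paths with little structural
#' bias.  `sigma_mode = "factor"` instead uses the common-factor
#' construction (within-block covariances `loading_i * loading_j`, unique
#' variances on the diagonal), under which composite estimands differ
#' systematically from the factor parameters.
#'
#' @param loadings Numeric vector of three standardized loadings used in
#'   every block.
#' @param exo_corr Correlation among the four exogenous components: either
#'   a single value (equicorrelation) or a 4 x 4 correlation matrix.
#' @param sigma_mode `"composite"` (default) or `"factor"`; see Details.
#' @param paths Path specification data frame with columns `from`, `to`,
#'   `value` (defaults to the built-in structure).
#' @return Object of class `gsca_population`: `model` (a [gsca_model()]),
#'   `true_loadings`, `true_paths` (the path data frame), `path_matrix`
#'   (P x P coefficients), `exo_corr`, `latent_cov` (6 x 6), `r2` (named,
#'   per endogenous component), `sigma` (18 x 18), `sigma_mode`,
#'   `weights_pop` (generating composite weights, composite mode only), and
#'   `theta_pop`, the labeled true parameter vector aligned with
#'   [gsca_fit()] parameter labels.
#' @examples
#' pop <- gsca_population()
#' round(pop$r2, 3)
#' @export
gsca_population <- function(loadings = c(0.7, 0.8, 0.9),
                            exo_corr = default_exo_rho,
                            sigma_mode = c("composite", "factor"),
                            paths = default_path_table()) {
  sigma_mode <- match.arg(sigma_mode)
  if (length(loadings) != 3 || any(loadings <= 0) || any(loadings >= 1))
    stop("`loadings` must be three values in (0, 1)")
  components <- paste0("gamma", 1:6)
  blocks <- setNames(lapply(1:6, function(p) sprintf("y%d%d", p, 1:3)),
                     components)
  model <- gsca_model(blocks, paths = paste(paths$from, "->", paths$to))

  if (is.matrix(exo_corr)) {
    if (!all(dim(exo_corr) == c(4, 4)))
      stop("`exo_corr` matrix must be 4 x 4")
    Phi_x <- exo_corr
  } else {
    Phi_x <- matrix(exo_corr, 4, 4); diag(Phi_x) <- 1
  }

  Bmat <- matrix(0, 6, 6, dimnames = list(components, components))
  Bmat[cbind(match(paths$from, components), match(paths$to, components))] <-
    paths$value

  lc <- build_latent_cov(Phi_x, Bmat, model$path_pattern, components)

  sig <- build_sigma(lc$Phi, loadings, sigma_mode)
  theta <- c(setNames(rep(loadings, 6), parameter_labels(model)$loadings),
             setNames(paths$value,
                      paste0(paths$from, "->", paths$to)))
  # align path labels with the canonical parameter order of gsca_fit
  lab <- parameter_labels(model)$all
  theta <- theta[lab]

  structure(list(
    model = model,
    true_loadings = loadings,
    true_paths = paths,
    path_matrix = Bmat,
    exo_corr = Phi_x,
    latent_cov = lc$Phi,
    r2 = lc$r2,
    sigma = sig$sigma,
    sigma_mode = sigma_mode,
    within_block_corr = sig$within_corr,
    weights_pop = sig$weights,
    theta_pop = theta
  ), class = "gsca_population")
}

## joint component correlation matrix by recursive substitution: endogenous
## components are built in an order where every predecessor already exists;
## residual variances are set so every component has unit variance.
build_latent_cov <- function(Phi_x, Bmat, patt, components) {
  P <- length(components)
  n_exo <- nrow(Phi_x)
  if (any(colSums(patt)[seq_len(n_exo)] > 0))
    stop("the first ", n_exo, " components are exogenous and cannot ",
         "receive paths")
  Phi <- diag(P)
  Phi[seq_len(n_exo), seq_len(n_exo)] <- Phi_x
  r2 <- setNames(numeric(0), character(0))
  remaining <- setdiff(seq_len(P), seq_len(n_exo))
  built <- seq_len(n_exo)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(p)
      all(which(patt[, p]) %in% built), TRUE)]
    if (!length(ready)) stop("structural paths contain a cycle")
    for (p in ready) {
      S <- which(patt[, p])
      if (!length(S)) { built <- c(built, p); next }  # independent component
      b <- Bmat[S, p]
      expl <- drop(crossprod(b, Phi[S, S, drop = FALSE] %*% b))
      if (expl >= 1)
        stop("implied residual variance of ", components[p],
             " is not positive (explained variance ", round(expl, 4), ")")
      cv <- as.vector(Phi[built, S, drop = FALSE] %*% b)
      Phi[built, p] <- Phi[p, built] <- cv
      Phi[p, p] <- 1
      r2[components[p]] <- expl
      built <- c(built, p)
    }
    remaining <- setdiff(remaining, ready)
  }
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied component correlation matrix is not positive definite")
  dimnames(Phi) <- list(components, components)
  list(Phi = Phi, r2 = r2)
}

## implied 18 x 18 indicator correlation matrix
build_sigma <- function(Phi, lam, sigma_mode) {
  P <- nrow(Phi); J <- 3 * P
  within_corr <- NA_real_; w <- NULL
  if (sigma_mode == "factor") {
    Spp <- outer(lam, lam); diag(Spp) <- 1
  } else {
    sol <- composite_block(lam)
    Spp <- sol$Spp; within_corr <- sol$r; w <- sol$w
  }
  sigma <- matrix(0, J, J)
  for (p in seq_len(P)) for (q in seq_len(P)) {
    ip <- (3 * p - 2):(3 * p); iq <- (3 * q - 2):(3 * q)
    sigma[ip, iq] <- if (p == q) Spp else Phi[p, q] * outer(lam, lam)
  }
  nm <- as.vector(t(outer(seq_len(P), 1:3, function(p, j)
    sprintf("y%d%d", p, j))))
  dimnames(sigma) <- list(nm, nm)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied indicator covariance matrix is not positive definite")
  list(sigma = sigma, within_corr = within_corr, weights = w)
}

## within-block equicorrelation r and weights w such that the unit-variance
## composite c = w'z satisfies cov(z, c) = lam exactly:
## solve (k-1) r^2 + (1 + A(k-1) - s^2) r + A = 0 with A = lam'lam - 1,
## s = sum(lam); the smaller root in (0, 1) is used.  For lam = (.7,.8,.9)
## this gives r = 1/2 and w = (0.2, 0.4, 0.6).
composite_block <- function(lam) {
  k <- length(lam)
  A <- sum(lam^2) - 1
  s <- sum(lam)
  qa <- k - 1
  qb <- 1 + A * (k - 1) - s^2
  qc <- A
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0) stop("no composite-consistent within-block correlation ",
                     "exists for these loadings")
  roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  r <- roots[roots > 0 & roots < 1][1]
  if (is.na(r)) stop("no admissible within-block correlation in (0, 1)")
  Spp <- matrix(r, k, k); diag(Spp) <- 1
  w <- (lam - r * s / (1 + (k - 1) * r)) / (1 - r)
  stopifnot(max(abs(Spp %*% w - lam)) < 1e-10,
            abs(sum(w * lam) - 1) < 1e-10)
  list(Spp = Spp, r = r, w = w)
}

#' Component correlation matrix implied by a population model
#'
#' @param pop A [gsca_population()].
#' @return The 6 x 6 implied component correlation matrix (unit diagonal).
#' @export
latent_covariance <- function(pop) {
  stopifnot(inherits(pop, "gsca_population"))
  pop$latent_cov
}

#' Explained variance of an endogenous component
#'
#' One minus the structural residual variance of an endogenous component
#' under unit-variance scaling, i.e. `b' Phi_pred b` for its incoming path
#' coefficients `b` and predictor correlation matrix `Phi_pred`.  A purely
#' structural quantity: it does not depend on the loadings.
#'
#' @param pop A [gsca_population()].
#' @param component Endogenous component name, e.g. `"gamma5"`.
#' @return Proportion of variance in `[0, 1)`.
#' @export
population_r2 <- function(pop, component) {
  stopifnot(inherits(pop, "gsca_population"))
  if (!component %in% names(pop$r2))
    stop("component '", component, "' has no structural predictors")
  unname(pop$r2[component])
}

#' Indicator correlation matrix implied by a population model
#'
#' @param pop A [gsca_population()].
#' @return The 18 x 18 implied indicator correlation matrix.
#' @export
implied_sigma <- function(pop) {
  stopifnot(inherits(pop, "gsca_population"))
  pop$sigma
}

#' Generate multivariate normal indicator data
#'
#' Rows are i.i.d. multivariate normal with covariance `implied_sigma(pop)`,
#' produced by mixing i.i.d. standard normal variates with the lower
#' Cholesky factor of sigma.
#'
#' @param pop A [gsca_population()].
#' @param n Number of observations (>= 20).
#' @param seed Integer seed.
#' @return n x 18 matrix with indicator column names.
#' @export
generate_normal <- function(pop, n, seed) {
  stopifnot(inherits(pop, "gsca_population"))
  if (n < 20) stop("`n` must be at least 20")
  L <- t(chol(pop$sigma))
  X <- with_seed(seed, matrix(rnorm(n * nrow(L)), n, nrow(L)))
  Y <- X %*% t(L)
  colnames(Y) <- colnames(pop$sigma)
  Y
}

#' Generate lognormal-transformed indicator data
#'
#' Independent standard normal variates are exponentiated into lognormal
#' variates, each column is standardized (divisor-n convention), and the
#' desired correlation structure is imposed by post-multiplying the matrix
#' by the transpose of the lower Cholesky factor of
#' `implied_sigma(pop)`.  The columns are strongly right-skewed and
#' leptokurtic while reproducing sigma in population.
#'
#' @inheritParams generate_normal
#' @return n x 18 matrix with indicator column names.
#' @export
generate_lognormal <- function(pop, n, seed) {
  stopifnot(inherits(pop, "gsca_population"))
  if (n < 20) stop("`n` must be at least 20")
  L <- t(chol(pop$sigma))
  X <- with_seed(seed, matrix(rnorm(n * nrow(L)), n, nrow(L)))
  Y <- gsca_standardize(exp(X)) %*% t(L)
  colnames(Y) <- colnames(pop$sigma)
  Y
}

#' Per-column skewness and kurtosis
#'
#' Third and fourth standardized sample moments of every column.  Kurtosis
#' is the plain fourth standardized moment (a normal distribution has
#' kurtosis 3); no excess adjustment is applied anywhere in the package.
#'
#' @param x Numeric matrix or data frame.
#' @return Data frame with columns `indicator`, `skewness`, `kurtosis`.
#' @export
sample_moments <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need at least 4 observations for a fourth moment")
  ctr <- sweep(x, 2, colMeans(x))
  m2 <- colMeans(ctr^2)
  if (any(m2 < 1e-24)) {
    bad <- which(m2 < 1e-24)
    nm <- if (is.null(colnames(x))) paste0("column ", bad) else
      colnames(x)[bad]
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  data.frame(
    indicator = if (is.null(colnames(x))) paste0("V", seq_len(ncol(x)))
                else colnames(x),
    skewness = colMeans(ctr^3) / m2^1.5,
    kurtosis = colMeans(ctr^4) / m2^2,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Replication-averaged indicator moments of a generator
#'
#' Generates `n_replications` datasets from the population model, computes
#' every indicator's sample skewness and kurtosis per replication, and
#' averages over replications.  The condition-level summary additionally
#' averages over the indicators, which is the aggregation under which the
#' generator's non-normality is reported.
#'
#' @param pop A [gsca_population()].
#' @param n Sample size per replication.
#' @param n_replications Number of replications.
#' @param seed Integer master seed; replication r uses `seed + r`.
#' @param dist `"lognormal"` (default) or `"normal"`.
#' @return List with `per_indicator` (data frame of replication-averaged
#'   skewness and kurtosis per indicator), `avg_skewness` and
#'   `avg_kurtosis` (averaged over replications and indicators), `n`, and
#'   `n_replications`.
#' @export
replication_moments <- function(pop, n, n_replications, seed,
                                dist = c("lognormal", "normal")) {
  dist <- match.arg(dist)
  gen <- if (dist == "lognormal") generate_lognormal else generate_normal
  J <- ncol(pop$sigma)
  sk <- matrix(0, n_replications, J)
  ku <- matrix(0, n_replications, J)
  for (r in seq_len(n_replications)) {
    m <- sample_moments(gen(pop, n, seed + r))
    sk[r, ] <- m$skewness
    ku[r, ] <- m$kurtosis
  }
  per_ind <- data.frame(indicator = colnames(pop$sigma),
                        skewness = colMeans(sk), kurtosis = colMeans(ku),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_indicator = per_ind,
       avg_skewness = mean(sk), avg_kurtosis = mean(ku),
       n = n, n_replications = n_replications)
}

#' @export
print.gsca_population <- function(x, ...) {
  cat("GSCA population model: 6 components, 18 indicators (",
      x$sigma_mode, " construction)\n", sep = "")
  cat("  loadings per block:", paste(x$true_loadings, collapse = ", "), "\n")
  cat("  paths:\n")
  for (i in seq_len(nrow(x$true_paths)))
    cat(sprintf("    %s -> %s : %g\n", x$true_paths$from[i],
                x$true_paths$to[i], x$true_paths$value[i]))
  cat("  explained variance:",
      paste(names(x$r2), "=", round(x$r2, 3), collapse = ", "), "\n")
  invisible(x)
}
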