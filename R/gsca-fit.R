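#' GSCA least-squares criterion
#'
#' Evaluates the single least-squares function that GSCA minimizes: the sum
#' of squared residuals of every indicator regressed on its own component
#' (measurement part) plus every endogenous component regressed on its
#' predecessors (structural part).  Component scores are the unit-variance
#' composites `Z w_p`.
#'
#' @param data Standardized n x J matrix (see [gsca_standardize()]).
#' @param model A [gsca_model()].
#' @param weights J x P weight matrix (zero where masked).
#' @param loadings P x J loading matrix (zero where masked).
#' @param paths P x P path coefficient matrix (zero where masked).
#' @return Non-negative scalar.
#' @export
fit_criterion <- function(data, model, weights, loadings, paths) {
  Z <- as.matrix(data)
  if (ncol(Z) != model$J) stop("data has ", ncol(Z), " columns, model has ",
                               model$J, " indicators")
  stopifnot(nrow(weights) == model$J, ncol(weights) == model$P,
            nrow(loadings) == model$P, ncol(loadings) == model$J,
            nrow(paths) == model$P, ncol(paths) == model$P)
  if (any(weights[!model$weight_pattern] != 0))
    stop("weights non-zero outside the weight pattern")
  if (any(loadings[!model$loading_pattern] != 0))
    stop("loadings non-zero outside the loading pattern")
  if (any(paths[!model$path_pattern] != 0))
    stop("paths non-zero outside the path pattern")
  Gamma <- Z %*% weights
  f <- sum((Z - Gamma %*% loadings)^2)
  for (p in which(colSums(model$path_pattern) > 0))
    f <- f + sum((Gamma[, p] - Gamma %*% paths[, p])^2)
  f
}

#' Fit a GSCA model by alternating least squares
#'
#' Minimizes the GSCA criterion (see [fit_criterion()]) by alternating two
#' exact least-squares steps: (i) given the weights, the free loadings and
#' path coefficients are per-column ordinary least squares solutions;
#' (ii) given loadings and paths, each component's free weights solve the
#' criterion's constrained least-squares subproblem under the unit-variance
#' normalization of the component score, sweeping components in index order.
#' Both steps are exact block minimizers, so the criterion value is
#' non-increasing across iterations.  All computations run on the J x J
#' cross-product matrix, so cost per iteration is independent of n.
#'
#' On convergence each component's sign is fixed so that the sum of its
#' loadings is non-negative.
#'
#' @param data n x J numeric matrix or data frame of indicators (columns
#'   named as in the model).
#' @param model A [gsca_model()].
#' @param init_weights Optional J x P starting weight matrix (e.g. a previous
#'   fit's weights, used to warm-start bootstrap refits).  The default starts
#'   every free weight at 1 before normalization.
#' @param tol Convergence tolerance: stop when the absolute decrease of the
#'   criterion falls below `tol`.
#' @param max_iter Maximum number of ALS iterations.
#' @param standardize Standardize `data` to the divisor-n convention first
#'   (default).  Set to `FALSE` only if `data` is already standardized.
#' @return An object of class `gsca_fit`: `weights` (J x P), `loadings`
#'   (P x J), `paths` (P x P), `fit` (criterion at the solution),
#'   `fit_history`, `n_iterations`, `converged`, `n`, and `parameters`, the
#'   flat named vector of free loadings and paths consumed by the bootstrap
#'   machinery.
#' @examples
#' m <- gsca_model(list(eta1 = c("x1", "x2")), NULL)
#' set.seed(1)
#' x1 <- rnorm(50); x2 <- 0.6 * x1 + 0.8 * rnorm(50)
#' fit <- gsca_fit(cbind(x1 = x1, x2 = x2), m)
#' coef(fit)
#' @export
gsca_fit <- function(data, model, init_weights = NULL, tol = 1e-5,
                     max_iter = 300, standardize = TRUE) {
  stopifnot(inherits(model, "gsca_model"))
  Z <- as.matrix(data)
  if (!is.null(colnames(Z)) && all(model$indicators %in% colnames(Z)))
    Z <- Z[, model$indicators, drop = FALSE]
  if (ncol(Z) != model$J)
    stop("data has ", ncol(Z), " columns, model expects ", model$J)
  if (standardize) Z <- gsca_standardize(Z)
  n <- nrow(Z)
  G <- crossprod(Z)
  res <- als_core(G, n, model, init_weights, tol, max_iter)

  dimnames(res$W) <- list(model$indicators, model$components)
  dimnames(res$C) <- list(model$components, model$indicators)
  dimnames(res$B) <- list(model$components, model$components)
  out <- structure(list(
    weights = res$W, loadings = res$C, paths = res$B,
    fit = res$fit, fit_history = res$fit_history,
    n_iterations = res$iter, converged = res$converged,
    n = n, model = model,
    parameters = extract_parameters(model, res$C, res$B)
  ), class = "gsca_fit")
  out
}

## ALS on the cross-product matrix G = Z'Z (divisor-n standardized Z, so
## diag(G) = n).  Weight update: for component p the criterion restricted to
## w_p is  const - 2 a'w + (sum of squared coefficients) * w'M w  with
## M = G[block, block]; under the normalization w'Mw = n the quadratic term
## is constant, so the constrained minimizer is w = sqrt(n) M^-1 a scaled to
## the constraint, which keeps the fit sequence monotone.
als_core <- function(G, n, model, init_weights, tol, max_iter) {
  J <- model$J; P <- model$P
  blocks <- model$blocks
  path <- model$path_pattern
  endo <- which(colSums(path) > 0)
  children <- lapply(seq_len(P), function(p) which(path[p, ]))

  W <- matrix(0, J, P)
  if (is.null(init_weights)) {
    for (p in seq_len(P)) W[blocks[[p]], p] <- 1
  } else {
    stopifnot(nrow(init_weights) == J, ncol(init_weights) == P)
    W[] <- init_weights
    W[!model$weight_pattern] <- 0
  }
  for (p in seq_len(P)) {
    v <- drop(crossprod(W[, p], G %*% W[, p]))
    if (v < 1e-12) stop_inadmissible("degenerate starting weights for block ",
                                     model$components[p])
    W[, p] <- W[, p] * sqrt(n / v)
  }

  C <- matrix(0, P, J)
  Bm <- matrix(0, P, P)
  GW <- G %*% W
  f_old <- Inf
  fit_history <- numeric(0)
  converged <- FALSE
  it <- 0

  solve_or_fail <- function(M, b, what) {
    out <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(out))
      stop_inadmissible(paste0("singular least-squares subproblem (", what,
                               "); collinear indicators within a block"))
    out
  }

  while (it < max_iter) {
    it <- it + 1L
    WG <- t(GW)                  # P x J  = W'G
    WGW <- crossprod(W, GW)      # P x P  = W'G W

    # loadings: c_pj = gamma_p' z_j / n for j in block p
    for (p in seq_len(P)) C[p, blocks[[p]]] <- WG[p, blocks[[p]]] / n
    # paths: per-column OLS among component scores
    for (p in endo) {
      S <- which(path[, p])
      Bm[, p] <- 0
      Bm[S, p] <- solve_or_fail(WGW[S, S, drop = FALSE], WGW[S, p], "paths")
    }
    # weights: coordinate-wise constrained least squares
    for (p in seq_len(P)) {
      bp <- blocks[[p]]
      a <- G[bp, bp, drop = FALSE] %*% C[p, bp]
      if (p %in% endo) a <- a + GW[bp, , drop = FALSE] %*% Bm[, p]
      for (q in children[[p]]) {
        bq <- Bm[, q]; bq[p] <- 0
        a <- a + Bm[p, q] * (GW[bp, q] - GW[bp, , drop = FALSE] %*% bq)
      }
      M <- G[bp, bp, drop = FALSE]
      # the normal equations M w = a are always consistent (a lies in the
      # range of M), so a rank-deficient block -- e.g. duplicated
      # indicators -- is solved by the minimum-norm solution
      w <- tryCatch(solve(M, a), error = function(e) psolve(M, a))
      sc <- drop(crossprod(w, M %*% w))
      if (sc < 1e-12) next        # degenerate direction: keep previous w_p
      w <- w * sqrt(n / sc)
      W[bp, p] <- w
      GW[, p] <- G[, bp, drop = FALSE] %*% w
    }

    WG <- t(GW); WGW <- crossprod(W, GW)
    f <- sum(diag(G)) - 2 * sum(C * WG) + sum((WGW %*% C) * C)
    for (p in endo) {
      b <- Bm[, p]
      f <- f + WGW[p, p] - 2 * sum(b * WGW[, p]) + drop(crossprod(b, WGW %*% b))
    }
    fit_history <- c(fit_history, f)
    if (f_old - f < tol) { converged <- TRUE; break }
    f_old <- f
  }

  # sign convention: sum of loadings per component >= 0
  for (p in seq_len(P)) {
    if (sum(C[p, ]) < 0) {
      W[, p] <- -W[, p]; C[p, ] <- -C[p, ]
      Bm[p, ] <- -Bm[p, ]; Bm[, p] <- -Bm[, p]
    }
  }
  list(W = W, C = C, B = Bm, fit = f, fit_history = fit_history,
       iter = it, converged = converged)
}

## minimum-norm solution of a symmetric PSD system via eigendecomposition
psolve <- function(M, b) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  if (!any(pos))
    stop_inadmissible("degenerate block: all indicators constant")
  v <- e$vectors[, pos, drop = FALSE]
  v %*% (crossprod(v, b) / e$values[pos])
}

extract_parameters <- function(model, loadings, paths) {
  lab <- parameter_labels(model)
  lv <- loadings[cbind(model$block_of, seq_len(model$J))]
  pv <- if (nrow(lab$path_idx)) paths[lab$path_idx] else numeric(0)
  setNames(c(lv, pv), lab$all)
}

#' Align the component signs of one fit to a reference fit
#'
#' GSCA components are sign-indeterminate: flipping a weight column together
#' with the corresponding loading row and path row/column leaves the
#' criterion unchanged.  Bootstrap and jackknife refits are aligned to the
#' original estimate so their parameter distributions are unimodal.  For
#' each component, the candidate's signs are flipped when the inner product
#' of candidate and reference weight vectors is negative; an inner product
#' of exactly zero keeps the candidate unchanged.
#'
#' @param candidate,reference `gsca_fit` objects for the same model.
#' @return The candidate with aligned signs (fit value unchanged).
#' @export
sign_align <- function(candidate, reference) {
  stopifnot(inherits(candidate, "gsca_fit"), inherits(reference, "gsca_fit"))
  if (!identical(candidate$model$components, reference$model$components) ||
      !identical(candidate$model$indicators, reference$model$indicators))
    stop("candidate and reference use different models")
  W <- candidate$weights; C <- candidate$loadings; B <- candidate$paths
  for (p in seq_len(candidate$model$P)) {
    if (sum(W[, p] * reference$weights[, p]) < 0) {
      W[, p] <- -W[, p]; C[p, ] <- -C[p, ]
      B[p, ] <- -B[p, ]; B[, p] <- -B[, p]
    }
  }
  candidate$weights <- W; candidate$loadings <- C; candidate$paths <- B
  candidate$parameters <- extract_parameters(candidate$model, C, B)
  candidate
}

#' @export
coef.gsca_fit <- function(object, ...) object$parameters

#' @export
print.gsca_fit <- function(x, digits = 4, ...) {
  cat("GSCA fit:", x$model$J, "indicators,", x$model$P, "components\n")
  cat("  criterion:", format(x$fit, digits = digits),
      " iterations:", x$n_iterations,
      " converged:", x$converged, "\n")
  cat("Loadings:\n")
  lv <- x$parameters[seq_len(x$model$J)]
  print(round(lv, digits))
  if (length(x$parameters) > x$model$J) {
    cat("Path coefficients:\n")
    print(round(x$parameters[-seq_len(x$model$J)], digits))
  }
  invisible(x)
}
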