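#' Define a Monte Carlo simulation design
#'
#' The full design crosses indicator distributions with sample sizes; every
#' cell is replicated `n_replications` times and every replication carries
#' one shared bootstrap pass of `B` resamples (plus one jackknife pass when
#' BCa intervals are requested).
#'
#' @param distributions Subset of `c("normal", "lognormal")`.
#' @param sample_sizes Integer vector of sample sizes.
#' @param n_replications Replications per cell.
#' @param B Bootstrap resamples per replication.
#' @param alpha Significance level of the intervals.
#' @param methods Subset of `c("percentile", "bca", "student_t")`.
#' @param master_seed Integer master seed; all cell and replication seeds
#'   are derived from it, so the study output is a pure function of the
#'   design.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(distributions = c("normal", "lognormal"),
                              sample_sizes = c(50, 100, 200, 500),
                              n_replications = 500,
                              B = 1000,
                              alpha = 0.05,
                              methods = c("percentile", "bca", "student_t"),
                              master_seed = 1) {
  distributions <- match.arg(distributions, c("normal", "lognormal"),
                             several.ok = TRUE)
  methods <- match.arg(methods, c("percentile", "bca", "student_t"),
                       several.ok = TRUE)
  if (n_replications < 1) stop("`n_replications` must be >= 1")
  if (B * alpha / 2 < 1) stop("need B * alpha/2 >= 1")
  structure(list(distributions = distributions,
                 sample_sizes = as.integer(sample_sizes),
                 n_replications = as.integer(n_replications),
                 B = as.integer(B), alpha = alpha, methods = methods,
                 master_seed = as.integer(master_seed)),
            class = "simulation_design")
}

#' Run one simulation replication
#'
#' Generates one sample from the population model, fits the GSCA model,
#' builds the bootstrap distribution (and, if BCa is requested, one
#' jackknife pass), and returns the requested confidence intervals for all
#' free parameters.  Percentile and BCa endpoints are order statistics of
#' the same bootstrap replicate set.
#'
#' @param pop A [gsca_population()].
#' @param dist `"normal"` or `"lognormal"`.
#' @param n Sample size.
#' @param B Bootstrap resamples.
#' @param alpha Significance level.
#' @param methods Interval methods to compute.
#' @param seed Integer seed for this replication (generation uses `seed`,
#'   the bootstrap pass uses a fixed offset of it).
#' @return Data frame with one row per (parameter, method):
#'   `parameter`, `method`, `level`, `estimate`, `se`, `lower`, `upper`,
#'   diagnostics, plus attributes `converged` (logical) and `n_failed`
#'   (redrawn resamples).
#' @export
run_replication <- function(pop, dist = c("normal", "lognormal"), n,
                            B = 1000, alpha = 0.05,
                            methods = c("percentile", "bca", "student_t"),
                            seed = 1) {
  dist <- match.arg(dist)
  methods <- match.arg(methods, c("percentile", "bca", "student_t"),
                       several.ok = TRUE)
  gen <- if (dist == "lognormal") generate_lognormal else generate_normal
  raw <- gen(pop, n, seed)
  fit <- gsca_fit(raw, pop$model)
  if (!fit$converged) {
    out <- data.frame()
    attr(out, "converged") <- FALSE
    attr(out, "n_failed") <- NA_integer_
    return(out)
  }
  bd <- gsca_bootstrap(raw, pop$model, fit, B = B, seed = seed + 104729L)
  jk <- if ("bca" %in% methods) gsca_jackknife(raw, pop$model, fit) else NULL
  out <- gsca_ci(bd, jk, methods = methods, alpha = alpha)
  attr(out, "converged") <- TRUE
  attr(out, "n_failed") <- bd$n_failed
  out
}

#' Run all replications of one design cell
#'
#' Replication r of a cell uses the derived seed `cell_seed + r`, so any
#' replication can be reproduced in isolation and the records do not depend
#' on execution order.  Replication failures are recorded as
#' non-converged rows, never dropped silently.
#'
#' @param pop A [gsca_population()].
#' @param dist,n The cell's distribution and sample size.
#' @param n_replications Number of replications.
#' @param B,alpha,methods As in [run_replication()].
#' @param cell_seed Integer base seed for the cell.
#' @param verbose Print progress every 50 replications.
#' @return Long-format data frame: one row per
#'   (replication, parameter, method) with the interval columns plus
#'   `distribution`, `n`, `replication`, `converged`, `n_failed`.
#' @export
run_condition <- function(pop, dist, n, n_replications,
                          B = 1000, alpha = 0.05,
                          methods = c("percentile", "bca", "student_t"),
                          cell_seed = 1, verbose = FALSE) {
  recs <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    rec <- run_replication(pop, dist, n, B = B, alpha = alpha,
                           methods = methods, seed = cell_seed + r)
    conv <- isTRUE(attr(rec, "converged"))
    if (!conv) {
      rec <- data.frame(parameter = NA_character_, method = NA_character_,
                        level = 1 - alpha, estimate = NA_real_,
                        se = NA_real_, lower = NA_real_, upper = NA_real_,
                        z0 = NA_real_, a = NA_real_, alpha1 = NA_real_,
                        alpha2 = NA_real_, stringsAsFactors = FALSE)
    }
    rec$distribution <- dist
    rec$n <- n
    rec$replication <- r
    rec$converged <- conv
    rec$n_failed <- attr(rec, "n_failed") %||% NA_integer_
    recs[[r]] <- rec
    if (verbose && r %% 50 == 0)
      message(dist, " n=", n, ": replication ", r, "/", n_replications)
  }
  do.call(rbind, recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full Monte Carlo study
#'
#' Iterates over all design cells (distribution x sample size), collects
#' the long-format interval records, and optionally persists them together
#' with a manifest describing the design and seeds.  The output is a pure
#' function of the design, including its master seed.
#'
#' @param design A [simulation_design()].
#' @param pop A [gsca_population()]; defaults to the built-in population.
#' @param out_dir Optional directory: writes `results.csv` (the records)
#'   and `manifest.json` (the design).
#' @param verbose Print cell-level progress.
#' @return The combined long-format data frame (invisibly also written to
#'   `out_dir` when given).
#' @export
run_study <- function(design, pop = gsca_population(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  cells <- expand.grid(dist = design$distributions,
                       n = design$sample_sizes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (verbose)
      message("cell ", i, "/", nrow(cells), ": ", cells$dist[i],
              ", n = ", cells$n[i])
    out[[i]] <- run_condition(
      pop, cells$dist[i], cells$n[i], design$n_replications,
      B = design$B, alpha = design$alpha, methods = design$methods,
      cell_seed = design$master_seed + 10000L * i, verbose = verbose)
  }
  res <- do.call(rbind, out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(design = unclass(design),
           population = list(loadings = pop$true_loadings,
                             sigma_mode = pop$sigma_mode,
                             paths = pop$true_paths),
           r_version = as.character(getRversion())),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
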