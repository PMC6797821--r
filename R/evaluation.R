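#' Coverage and balance of confidence intervals against population values
#'
#' For every (distribution, n, method, parameter) group in a long-format
#' results table, computes the proportion of replications whose interval
#' contains the population value (coverage, inclusive endpoints:
#' `lower <= theta <= upper`), the proportion where the population value
#' falls below the lower limit (`miss_below`), and above the upper limit
#' (`miss_above`).  The three proportions form an exact ternary partition:
#' they sum to one in every group.  Non-converged replications are excluded
#' and reported via `n_effective`.
#'
#' @param records Long-format data frame from [run_study()] /
#'   [run_condition()] (columns `distribution`, `n`, `replication`,
#'   `parameter`, `method`, `lower`, `upper`, `converged`).
#' @param theta_pop Named numeric vector of population values covering
#'   every parameter present.
#' @return Data frame keyed by (distribution, n, method, parameter) with
#'   `coverage`, `miss_below`, `miss_above`, `n_effective`.
#' @export
coverage_balance <- function(records, theta_pop) {
  ok <- records$converged & !is.na(records$parameter)
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no usable replications")
  missing <- setdiff(unique(rec$parameter), names(theta_pop))
  if (length(missing))
    stop("no population value for parameter(s): ",
         paste(missing, collapse = ", "))
  theta <- theta_pop[rec$parameter]
  rec$covered <- as.numeric(rec$lower <= theta & theta <= rec$upper)
  rec$below <- as.numeric(theta < rec$lower)
  rec$above <- as.numeric(theta > rec$upper)
  agg <- aggregate(cbind(covered, below, above) ~
                     distribution + n + method + parameter,
                   data = rec, FUN = mean)
  cnt <- aggregate(cbind(n_effective = covered) ~
                     distribution + n + method + parameter,
                   data = rec, FUN = length)
  out <- merge(agg, cnt,
               by = c("distribution", "n", "method", "parameter"))
  names(out)[names(out) == "covered"] <- "coverage"
  names(out)[names(out) == "below"] <- "miss_below"
  names(out)[names(out) == "above"] <- "miss_above"
  out[order(out$distribution, out$n, out$method, out$parameter), ,
      drop = FALSE]
}

#' Aggregate loading summaries over components sharing a loading value
#'
#' Loadings take one of three population values per block (e.g. 0.7, 0.8,
#' 0.9); performance is reported per loading value as the unweighted mean
#' of the six per-component summaries sharing that value.
#'
#' @param summaries Output of [coverage_balance()].
#' @param theta_pop Named population vector (used to map each loading
#'   parameter to its value).
#' @return Data frame keyed by (distribution, n, method, `loading`) with
#'   averaged `coverage`, `miss_below`, `miss_above` and summed
#'   `n_effective`.
#' @export
aggregate_loadings <- function(summaries, theta_pop) {
  s <- summaries[grepl("->y", summaries$parameter, fixed = TRUE), ,
                 drop = FALSE]
  if (!nrow(s)) stop("no loading parameters in the summaries")
  s$loading <- unname(theta_pop[s$parameter])
  if (anyNA(s$loading)) stop("missing population loading value")
  aggregate_group(s, "loading")
}

#' Aggregate path summaries over loading conditions
#'
#' Path-coefficient performance is reported per population path value,
#' averaged (unweighted) over whatever loading conditions are present.
#'
#' @inheritParams aggregate_loadings
#' @return Data frame keyed by (distribution, n, method, `path_value`).
#' @export
aggregate_paths <- function(summaries, theta_pop) {
  s <- summaries[!grepl("->y", summaries$parameter, fixed = TRUE), ,
                 drop = FALSE]
  if (!nrow(s)) stop("no path parameters in the summaries")
  s$path_value <- unname(theta_pop[s$parameter])
  if (anyNA(s$path_value)) stop("missing population path value")
  aggregate_group(s, "path_value")
}

aggregate_group <- function(s, key) {
  f <- stats::as.formula(paste(
    "cbind(coverage, miss_below, miss_above) ~ distribution + n + method +",
    key))
  agg <- aggregate(f, data = s, FUN = mean)
  cnt <- aggregate(stats::as.formula(paste("n_effective ~",
                                           "distribution + n + method +",
                                           key)),
                   data = s, FUN = sum)
  out <- merge(agg, cnt, by = c("distribution", "n", "method", key))
  out[order(out$distribution, out$n, out$method, out[[key]]), ,
      drop = FALSE]
}

#' Score a full study: per-parameter, per-loading and per-path summaries
#'
#' Pure function of the results table: scoring the same records twice
#' yields identical summaries.
#'
#' @param records Long-format results from [run_study()].
#' @param pop The [gsca_population()] that generated them.
#' @return List with `by_parameter`, `by_loading`, `by_path`.
#' @export
evaluate_study <- function(records, pop) {
  stopifnot(inherits(pop, "gsca_population"))
  by_par <- coverage_balance(records, pop$theta_pop)
  list(by_parameter = by_par,
       by_loading = aggregate_loadings(by_par, pop$theta_pop),
       by_path = aggregate_paths(by_par, pop$theta_pop))
}
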