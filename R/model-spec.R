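#' Specify a GSCA measurement and structural model
#'
#' A GSCA model assigns every indicator to exactly one component (a block)
#' and declares which directed paths between components are free.  The
#' component for each block is an exact weighted composite of its indicators,
#' constrained to unit variance; loadings are the regression (equivalently,
#' correlation-metric) coefficients from a component back onto its own
#' indicators.
#'
#' @param blocks Named list.  Each element is a character vector of indicator
#'   names belonging to that component; the element name is the component
#'   name.  Every indicator must appear in exactly one block.
#' @param paths Character vector of directed paths `"from -> to"` between
#'   component names, or `NULL` for a measurement-only model.  Self-paths are
#'   not allowed.
#' @return An object of class `gsca_model` with elements
#'   `indicators`, `components`, `J`, `P`, `block_of` (integer vector mapping
#'   indicator to component index), `blocks` (list of indicator index
#'   vectors), `weight_pattern` (J x P logical), `loading_pattern`
#'   (P x J logical), and `path_pattern` (P x P logical, `[i, j]` meaning a
#'   path from component i to component j).
#' @examples
#' m <- gsca_model(
#'   blocks = list(eta1 = c("x1", "x2", "x3"), eta2 = c("y1", "y2")),
#'   paths  = "eta1 -> eta2")
#' m
#' @export
gsca_model <- function(blocks, paths = NULL) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("`blocks` must be a fully named list of indicator name vectors")
  components <- names(blocks)
  if (anyDuplicated(components))
    stop("duplicated component names in `blocks`")
  indicators <- unlist(blocks, use.names = FALSE)
  if (!is.character(indicators))
    stop("block members must be character indicator names")
  if (anyDuplicated(indicators))
    stop("each indicator must belong to exactly one block; duplicated: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "))
  J <- length(indicators)
  P <- length(components)
  block_of <- rep(seq_len(P), lengths(blocks))
  names(block_of) <- indicators

  weight_pattern <- matrix(FALSE, J, P,
                           dimnames = list(indicators, components))
  for (p in seq_len(P)) weight_pattern[block_of == p, p] <- TRUE

  path_pattern <- matrix(FALSE, P, P, dimnames = list(components, components))
  for (pth in parse_paths(paths, components)) {
    if (pth[1] == pth[2]) stop("self-path not allowed: ", pth[1])
    path_pattern[pth[1], pth[2]] <- TRUE
  }

  structure(list(
    indicators = indicators,
    components = components,
    J = J, P = P,
    block_of = block_of,
    blocks = lapply(seq_len(P), function(p) which(block_of == p)),
    weight_pattern = weight_pattern,
    loading_pattern = t(weight_pattern),
    path_pattern = path_pattern
  ), class = "gsca_model")
}

parse_paths <- function(paths, components) {
  if (is.null(paths) || length(paths) == 0) return(list())
  out <- lapply(paths, function(s) {
    parts <- trimws(strsplit(s, "->", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(parts == ""))
      stop("malformed path specification: '", s, "' (expected 'from -> to')")
    missing <- setdiff(parts, components)
    if (length(missing))
      stop("unknown component in path '", s, "': ",
           paste(missing, collapse = ", "))
    parts
  })
  out
}

#' Read a model specification from a plain-text config
#'
#' The config lists one block per line as `component: ind1, ind2, ind3` and
#' one path per line as `from -> to`.  Blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path Path to the config file, or a character vector of config lines
#'   (anything of length > 1, or containing a newline, is treated as
#'   literal content).
#' @return A [gsca_model()] object.
#' @export
read_model_config <- function(path) {
  lines <- if (length(path) > 1 || grepl("\n", path[1], fixed = TRUE)) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_path <- grepl("->", lines, fixed = TRUE)
  blocks <- list()
  for (ln in lines[!is_path]) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed block line: '", ln, "' (expected 'component: i1, i2')")
    inds <- trimws(strsplit(gsub("\\[|\\]", "", parts[2]), ",")[[1]])
    blocks[[trimws(parts[1])]] <- inds[nzchar(inds)]
  }
  if (!length(blocks)) stop("config defines no blocks")
  gsca_model(blocks, paths = if (any(is_path)) lines[is_path] else NULL)
}

#' @export
print.gsca_model <- function(x, ...) {
  cat("GSCA model:", x$J, "indicators,", x$P, "components,",
      sum(x$path_pattern), "structural paths\n")
  for (p in seq_len(x$P))
    cat("  ", x$components[p], ": ",
        paste(x$indicators[x$blocks[[p]]], collapse = ", "), "\n", sep = "")
  ij <- which(x$path_pattern, arr.ind = TRUE)
  if (nrow(ij))
    cat("  paths:",
        paste(x$components[ij[, 1]], "->", x$components[ij[, 2]],
              collapse = "; "), "\n")
  invisible(x)
}

## labels of the free parameter vector: all free loadings (by block, in
## indicator order) followed by all free paths (column-major over the mask)
parameter_labels <- function(model) {
  load_lab <- paste0(model$components[model$block_of], "->", model$indicators)
  ij <- which(model$path_pattern, arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
  path_lab <- if (nrow(ij))
    paste0(model$components[ij[, 1]], "->", model$components[ij[, 2]])
  else character(0)
  list(loadings = load_lab, paths = path_lab,
       all = c(load_lab, path_lab), path_idx = ij)
}
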