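#' Standardize indicator data to the divisor-n convention
#'
#' Centers every column to mean zero and scales it so that its sum of squares
#' equals the number of rows, i.e. variance one under the divisor-n
#' convention.  GSCA operates on the correlational metric, and this scaling
#' makes the unit-variance normalization of component scores
#' (`diag(W'Z'ZW) = n I`) exact.
#'
#' @param x Numeric matrix or data frame, rows are observations.
#' @return A numeric matrix of the same dimension with column means 0 and
#'   column sums of squares equal to `nrow(x)`.  Idempotent.
#' @examples
#' z <- gsca_standardize(cbind(a = c(1, 2, 3), b = c(2, 1, 4)))
#' colMeans(z)            # ~0
#' colSums(z^2)           # = 3
#' @export
gsca_standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric")
  n <- nrow(x)
  if (n < 3) stop("at least 3 observations are required, got ", n)
  if (anyNA(x)) stop("missing values are not supported")
  cn <- colnames(x)
  ctr <- sweep(x, 2, colMeans(x))
  s <- sqrt(colMeans(ctr^2))
  bad <- which(s < 1e-12)
  if (length(bad)) {
    nm <- if (is.null(cn)) paste0("column ", bad) else cn[bad]
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  sweep(ctr, 2, s, "/")
}
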