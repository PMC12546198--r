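#' Samples-by-neurons activity matrix
#'
#' Container for the matrix whose columns hold one time series per neuron
#' (binary spike raster binned in time, or membrane voltages) and whose P
#' rows are time samples. The synchrony metric requires P >= N and is
#' only accurate when P is much larger than N.
#'
#' @param values numeric P x N matrix.
#' @param sample_ms sample period (ms).
#' @param labels optional column (neuron) labels.
#' @export
rasterMatrix <- function(values, sample_ms = 1, labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) colnames(values) <- labels
  structure(list(values = values, sample_ms = sample_ms),
            class = "raster_matrix")
}

#' @export
print.raster_matrix <- function(x, ...) {
  cat(sprintf("<raster_matrix> %d samples x %d neurons at %g ms\n",
              nrow(x$values), ncol(x$values), x$sample_ms))
  invisible(x)
}

.as_gamma <- function(gamma) {
  if (inherits(gamma, "raster_matrix")) gamma$values else as.matrix(gamma)
}

#' Covariance complexity of population activity
#'
#' Columns are mean-centered (so DC offsets cannot masquerade as
#' synchrony) and by default also scaled to unit variance, so the index
#' measures the correlation structure of the population rather than the
#' concentration of raw variance: without scaling, a small subpopulation
#' with much larger per-neuron variance (e.g. a handful of tonically
#' driven cells in an otherwise sparse raster) dominates the singular
#' spectrum and masquerades as network synchrony. Identically-constant
#' columns (silent neurons) are dropped, and the singular values
#' \eqn{\lambda_i} of the standardized matrix computed. The
#' variance fraction carried by component i is
#' \eqn{\sigma_i = \lambda_i^2 / \sum_j \lambda_j^2}, and the covariance
#' complexity is the normalized spectral entropy
#' \eqn{C = -(1/\log N) \sum_k \sigma_k \log \sigma_k} (with
#' \eqn{0 \log 0 = 0}; natural log — C is base-invariant thanks to the
#' \eqn{1/\log N} normalization). C is 0 when one component carries all
#' variance and 1 when all N components carry equal variance.
#'
#' @param gamma a [rasterMatrix()] or plain P x N matrix, P >= N >= 2.
#' @param scale scale each centered column to unit variance (default
#'   TRUE); FALSE gives the plain mean-centered variant.
#' @param details if TRUE, return a list with C, the variance fractions,
#'   the effective N and the number of dropped silent columns.
#' @return C in [0, 1] (or the detail list).
#' @export
covarianceComplexity <- function(gamma, scale = TRUE, details = FALSE) {
  m <- .as_gamma(gamma)
  if (ncol(m) < 2) stop("need at least 2 neurons")
  if (nrow(m) < ncol(m)) stop("need at least as many samples as neurons")
  m <- base::scale(m, center = TRUE, scale = FALSE)
  live <- colSums(m != 0) > 0
  dropped <- sum(!live)
  m <- m[, live, drop = FALSE]
  if (scale && ncol(m) >= 2) m <- base::scale(m, center = FALSE,
                                              scale = apply(m, 2, stats::sd))
  N <- ncol(m)
  if (N < 2 || all(m == 0))
    stop("matrix is all-zero after centering; complexity undefined")
  lambda <- svd(m, nu = 0, nv = 0)$d
  sig <- lambda^2 / sum(lambda^2)
  terms <- ifelse(sig > 0, sig * log(sig), 0)
  C <- -sum(terms) / log(N)
  C <- min(max(C, 0), 1)
  if (details)
    list(C = C, sigma = sig, N = N, P = nrow(m), dropped = dropped)
  else C
}

#' Morgera's index of synchrony
#'
#' \code{M = 1 - C}, where C is the covariance complexity: M = 1 for a
#' fully synchronized population (all columns identical up to scale) and
#' M tends to 0 for fully independent random activity.
#'
#' @inheritParams covarianceComplexity
#' @return M in [0, 1].
#' @export
morgeraIndex <- function(gamma, scale = TRUE)
  1 - covarianceComplexity(gamma, scale = scale)

#' Synchrony report for a samples-by-neurons matrix
#'
#' Emits M, C, effective N, P and the silent-column drop count — the
#' JSON-ready metric record.
#'
#' @inheritParams covarianceComplexity
#' @export
synchronyReport <- function(gamma) {
  d <- covarianceComplexity(gamma, details = TRUE)
  list(M = 1 - d$C, C = d$C, N = d$N, P = d$P, dropped_columns = d$dropped)
}
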