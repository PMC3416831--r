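#' Per-time sample moments of a data tensor
#'
#' Computes, for every observation time, the sample mean vector and (for
#' `order >= 2`) the sample covariance matrix of the observed components
#' across replicates. The covariance uses the unbiased estimator with divisor
#' `N - 1` by default; divisor `N` is available via `divisor = "N"`.
#'
#' @param data a `data_tensor` from [simulate_ensemble()] or
#'   [read_data_tensor()].
#' @param order highest moment order, 1 (means only) or 2 (means and
#'   covariances).
#' @param divisor `"N-1"` (unbiased, default) or `"N"`.
#' @return a `sample_moment_series`: list with `times`, `order`, `mean`
#'   (`K x d` matrix), `cov` (`K x d x d` array, `order >= 2` only), `N`.
#' @export
compute_sample_moments <- function(data, order = 2, divisor = c("N-1", "N")) {
  stopifnot(inherits(data, "data_tensor"), order %in% c(1, 2))
  divisor <- match.arg(divisor)
  N <- data$N
  K <- length(data$times)
  d <- length(data$observed)
  if (order >= 2 && N < 2)
    stop("covariance estimation needs at least 2 replicates (N = ", N, ")")
  if (order >= 2 && N <= d)
    warning("N <= number of observed components; sample covariances are ",
            "degenerate - consider more replicates")

  mean_mat <- matrix(0, K, d)
  cov_arr <- if (order >= 2) array(0, c(K, d, d)) else NULL
  for (k in seq_len(K)) {
    slab <- matrix(data$values[, k, ], N, d)
    mean_mat[k, ] <- colMeans(slab)
    if (order >= 2) {
      V <- stats::cov(slab)
      if (divisor == "N") V <- V * (N - 1) / N
      cov_arr[k, , ] <- V
    }
  }
  structure(list(times = data$times, order = order, mean = mean_mat,
                 cov = cov_arr, N = N, observed = data$observed),
            class = "sample_moment_series")
}

#' @export
print.sample_moment_series <- function(x, ...) {
  cat(sprintf("<sample_moment_series: order %d, %d times, %d components, N = %d>\n",
              x$order, length(x$times), ncol(x$mean), x$N))
  invisible(x)
}

# wrap externally supplied / model-generated moment curves in the same
# container so cost functions accept exact-moment surrogate data
as_moment_series <- function(times, mean, cov = NULL, N = Inf) {
  mean <- as.matrix(mean)
  structure(list(times = times, order = if (is.null(cov)) 1 else 2,
                 mean = mean, cov = cov, N = N,
                 observed = seq_len(ncol(mean))),
            class = "sample_moment_series")
}
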