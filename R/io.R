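#' Write / read an ensemble data tensor
#'
#' The tensor is stored as long-format CSV with columns `replicate`, `time`,
#' `species`, `count`, plus a JSON sidecar (`<file>.json`) recording seed,
#' parameters, model name, observed indices and package version for
#' provenance. `read_data_tensor()` reverses the round trip exactly.
#'
#' @param data a `data_tensor`.
#' @param file CSV path (sidecar written next to it).
#' @return `write_data_tensor()` the file path, invisibly;
#'   `read_data_tensor()` a `data_tensor`.
#' @export
write_data_tensor <- function(data, file) {
  stopifnot(inherits(data, "data_tensor"))
  K <- length(data$times)
  d <- length(data$observed)
  df <- data.frame(
    replicate = rep(seq_len(data$N), times = K * d),
    time = rep(rep(data$times, each = data$N), times = d),
    species = rep(data$observed, each = data$N * K),
    count = as.vector(data$values))
  utils::write.csv(df, file, row.names = FALSE)
  meta <- list(seed = data$seed, params = as.list(data$params),
               model = data$model, observed = data$observed, N = data$N,
               times = data$times,
               package_version = as.character(utils::packageVersion("stokinfit")))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_data_tensor
#' @export
read_data_tensor <- function(file) {
  df <- utils::read.csv(file)
  meta <- if (file.exists(paste0(file, ".json")))
    jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  else list()
  times <- sort(unique(df$time))
  observed <- sort(unique(df$species))
  N <- max(df$replicate)
  values <- array(0, c(N, length(times), length(observed)))
  df <- df[order(match(df$species, observed), match(df$time, times),
                 df$replicate), ]
  values[] <- df$count
  structure(list(values = values, times = times, observed = observed, N = N,
                 seed = meta$seed,
                 params = unlist(meta$params),
                 model = if (is.null(meta$model)) "unknown" else meta$model),
            class = "data_tensor")
}

#' Write / read a sample moment series as tidy CSV
#'
#' Columns are `time`, `statistic` (`"mean"` or `"cov"`), `component_i`,
#' `component_j` (`NA` for means), `value`.
#'
#' @param sms a `sample_moment_series` (or `moment_trajectory`, exported in
#'   the same layout with its covariance block).
#' @param file CSV path.
#' @export
write_moment_series <- function(sms, file) {
  K <- length(sms$times)
  d <- ncol(sms$mean)
  rows <- data.frame(time = rep(sms$times, each = d),
                     statistic = "mean",
                     component_i = rep(seq_len(d), times = K),
                     component_j = NA_integer_,
                     value = as.numeric(t(sms$mean)))
  if (!is.null(sms$cov)) {
    pidx <- sym_pack_index(d)
    cv <- do.call(rbind, lapply(seq_len(K), function(k) {
      data.frame(time = sms$times[k], statistic = "cov",
                 component_i = pidx[, 1], component_j = pidx[, 2],
                 value = matrix(sms$cov[k, , ], d, d)[pidx])
    }))
    rows <- rbind(rows, cv)
  }
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_moment_series
#' @export
read_moment_series <- function(file) {
  df <- utils::read.csv(file)
  times <- sort(unique(df$time))
  K <- length(times)
  mean_rows <- df[df$statistic == "mean", ]
  d <- max(mean_rows$component_i)
  mean_mat <- matrix(0, K, d)
  for (r in seq_len(nrow(mean_rows)))
    mean_mat[match(mean_rows$time[r], times), mean_rows$component_i[r]] <-
      mean_rows$value[r]
  cov_arr <- NULL
  cov_rows <- df[df$statistic == "cov", ]
  if (nrow(cov_rows)) {
    cov_arr <- array(0, c(K, d, d))
    for (r in seq_len(nrow(cov_rows))) {
      k <- match(cov_rows$time[r], times)
      i <- cov_rows$component_i[r]; j <- cov_rows$component_j[r]
      cov_arr[k, i, j] <- cov_arr[k, j, i] <- cov_rows$value[r]
    }
  }
  as_moment_series(times, mean_mat, cov_arr)
}

#' Write a fit result, chain, or report as JSON (+ CSV traces)
#'
#' `write_fit_result()` writes `<prefix>.json` (estimates, cost, iteration
#' count, termination) and `<prefix>_trace.csv` (accepted iterates and cost
#' trace). `write_chain()` writes `<prefix>.json` (acceptance rate, priors,
#' seed) and `<prefix>_samples.csv`.
#'
#' @param fit a `fit_result`.
#' @param chain a `chain`.
#' @param prefix output path prefix.
#' @name result_io
NULL

#' @rdname result_io
#' @export
write_fit_result <- function(fit, prefix) {
  jsonlite::write_json(list(
    c_hat = as.list(fit$c_hat), cost = fit$cost,
    n_iterations = fit$n_iterations, termination = fit$termination,
    rel_errors = fit$rel_errors,
    package_version = as.character(utils::packageVersion("stokinfit"))),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  tr <- data.frame(iteration = seq_along(fit$cost_trace),
                   cost = fit$cost_trace)
  if (!is.null(fit$iterates) && nrow(fit$iterates) == nrow(tr))
    tr <- cbind(tr, as.data.frame(fit$iterates))
  utils::write.csv(tr, paste0(prefix, "_trace.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname result_io
#' @export
write_chain <- function(chain, prefix) {
  jsonlite::write_json(list(
    acceptance_rate = chain$acceptance_rate, burn_in = chain$burn_in,
    seed = chain$seed, priors = chain$priors,
    proposal_sd = chain$proposal_sd,
    package_version = as.character(utils::packageVersion("stokinfit"))),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(chain$samples),
                   paste0(prefix, "_samples.csv"), row.names = FALSE)
  invisible(prefix)
}
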