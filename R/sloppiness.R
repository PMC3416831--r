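#' Hessian of a moment-fitting cost
#'
#' Two constructions are available. `"gauss_newton"` builds `2 J' J` from
#' the residual Jacobian `J` (central finite differences on the residual
#' vector), which equals the exact Hessian at zero-residual minimizers.
#' `"finite_difference"` takes central second differences of the scalar
#' cost. With `scale = "log"` derivatives are taken with respect to
#' `theta = log(c)`, so that eigen-directions measure relative parameter
#' changes — the appropriate scale when parameters have different units; at a
#' stationary point this equals `diag(c) H diag(c)`.
#'
#' @param spec a [cost_spec()].
#' @param c evaluation point (positive).
#' @param method `"gauss_newton"` or `"finite_difference"`.
#' @param scale `"linear"` or `"log"`.
#' @param rel_step relative step for the finite differences.
#' @return symmetric `n_params x n_params` matrix.
#' @export
cost_hessian <- function(spec, c, method = c("gauss_newton", "finite_difference"),
                         scale = c("linear", "log"), rel_step = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  np <- length(c)
  if (method == "gauss_newton") {
    if (is.null(rel_step)) rel_step <- 1e-6
    r0 <- moment_residuals(c, spec)
    J <- matrix(0, length(r0), np)
    for (i in seq_len(np)) {
      h <- rel_step * abs(c[i])
      cp <- c; cp[i] <- c[i] + h
      cm <- c; cm[i] <- c[i] - h
      J[, i] <- tryCatch((moment_residuals(cp, spec) -
                            moment_residuals(cm, spec)) / (2 * h),
                         error = function(e)
                           stop("residual evaluation failed while probing ",
                                "parameter ", i, ": ", conditionMessage(e)))
    }
    if (scale == "log") J <- J %*% diag(c, nrow = np)
    H <- 2 * crossprod(J)
  } else {
    if (is.null(rel_step)) rel_step <- 1e-4
    f <- if (scale == "log") {
      function(th) moment_cost(exp(th), spec)
    } else {
      function(cc) moment_cost(cc, spec)
    }
    x <- if (scale == "log") log(c) else c
    hh <- rel_step * pmax(abs(x), 1e-3)
    f0 <- f(x)
    H <- matrix(0, np, np)
    probe <- function(z) tryCatch(f(z), error = function(e)
      stop("cost evaluation failed at a Hessian probe point: ",
           conditionMessage(e)))
    for (i in seq_len(np)) {
      ei <- replace(rep(0, np), i, hh[i])
      H[i, i] <- (probe(x + ei) - 2 * f0 + probe(x - ei)) / hh[i]^2
      for (j in seq_len(np)) {
        if (j <= i) next
        ej <- replace(rep(0, np), j, hh[j])
        H[i, j] <- H[j, i] <-
          (probe(x + ei + ej) - probe(x + ei - ej) -
             probe(x - ei + ej) + probe(x - ei - ej)) / (4 * hh[i] * hh[j])
      }
    }
  }
  H <- (H + t(H)) / 2
  dimnames(H) <- list(spec$net$param_names, spec$net$param_names)
  H
}

#' Sloppiness report from a Hessian
#'
#' Eigen-decomposes a symmetric Hessian, orders eigenvalues descending, and
#' classifies directions whose eigenvalue falls below
#' `tolerance * largest eigenvalue` as sloppy (practically non-identifiable).
#' The condition number is the ratio of extreme eigenvalues, `Inf` when the
#' smallest is at or below the tolerance.
#'
#' @param H symmetric matrix (e.g. from [cost_hessian()]).
#' @param tolerance relative eigenvalue threshold for sloppiness.
#' @return a `sloppiness_report`: list with `eigenvalues` (descending),
#'   `eigenvectors` (unit columns), `condition_number`, `sloppy` (logical per
#'   direction), `tolerance`.
#' @export
sloppiness_report <- function(H, tolerance = 1e-10) {
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("Hessian is not symmetric within tolerance")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- e$values
  sloppy <- lam <= tolerance * max(lam)
  cond <- if (any(sloppy)) Inf else max(lam) / min(lam)
  structure(list(eigenvalues = lam, eigenvectors = e$vectors,
                 condition_number = cond, sloppy = sloppy,
                 tolerance = tolerance),
            class = "sloppiness_report")
}

#' @export
print.sloppiness_report <- function(x, ...) {
  cat("<sloppiness_report>\n  eigenvalues: ",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n  condition number: ", format(x$condition_number),
      "\n  sloppy directions: ", sum(x$sloppy), "\n", sep = "")
  invisible(x)
}

#' Cost values on a two-direction parameter grid
#'
#' Evaluates the cost on `center + s1 * d1 + s2 * d2` over a rectangular grid
#' of offsets, for contour plots and ridge-line scans. Grid points outside
#' the positive orthant yield `NA`.
#'
#' @param spec a [cost_spec()].
#' @param center positive parameter vector at the grid center.
#' @param directions `n_params x 2` matrix of scan directions.
#' @param grid list of two numeric offset vectors.
#' @return matrix of cost values (`length(grid[[1]]) x length(grid[[2]])`).
#' @export
levelset_scan <- function(spec, center, directions, grid) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 2, length(grid) == 2)
  out <- matrix(NA_real_, length(grid[[1]]), length(grid[[2]]),
                dimnames = list(signif(grid[[1]], 6), signif(grid[[2]], 6)))
  for (i in seq_along(grid[[1]])) {
    for (j in seq_along(grid[[2]])) {
      cc <- center + grid[[1]][i] * directions[, 1] + grid[[2]][j] * directions[, 2]
      if (all(cc > 0))
        out[i, j] <- tryCatch(moment_cost(cc, spec), error = function(e) NA_real_)
    }
  }
  out
}
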