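#' Interpolated expression series with analytic derivatives
#'
#' Container for the dense, polynomial-smoothed series the optimizer
#' consumes: fitted values and their analytic derivatives on an equally
#' spaced grid, plus the per-gene polynomial degree chosen.
#'
#' @param values,derivatives genes x n_points matrices.
#' @param times dense equally spaced grid.
#' @param fit_degree integer vector of per-gene polynomial degrees.
#' @param gene_names character gene identifiers.
#' @return object of class `grn_interp`.
#' @export
grn_interp <- function(values, derivatives, times, fit_degree, gene_names) {
  stopifnot(
    is.matrix(values), is.matrix(derivatives),
    all(dim(values) == dim(derivatives)),
    ncol(values) == length(times),
    nrow(values) == length(gene_names)
  )
  if (any(!is.finite(values)) || any(!is.finite(derivatives))) {
    stop_bad("non-finite interpolated values")
  }
  dimnames(values) <- dimnames(derivatives) <- list(gene_names, NULL)
  structure(
    list(
      values = values, derivatives = derivatives, times = as.numeric(times),
      fit_degree = as.integer(fit_degree), gene_names = as.character(gene_names)
    ),
    class = "grn_interp"
  )
}

#' @export
print.grn_interp <- function(x, ...) {
  cat(sprintf(
    "<grn_interp> %d genes x %d points, t in [%g, %g], degrees %s\n",
    nrow(x$values), ncol(x$values), min(x$times), max(x$times),
    paste(range(x$fit_degree), collapse = "-")
  ))
  invisible(x)
}

#' Polynomial interpolation of a time course
#'
#' Fits one global least-squares polynomial per gene and evaluates it, with
#' its analytic derivative, on a dense equally spaced grid spanning the
#' original time range. The per-gene degree is chosen between 2 and
#' `max_degree` by leave-one-out cross-validation error (computed from the
#' hat matrix), which keeps smooth trajectories smooth without ringing.
#' The time axis is rescaled to \[0, 1\] before fitting for conditioning.
#'
#' @param tc a single-replicate [grn_timecourse()] (see
#'   [average_replicates()]).
#' @param n_points number of dense grid points (default 200).
#' @param max_degree maximum polynomial degree considered (default 6).
#' @return a [grn_interp()].
#' @export
interpolate_timecourse <- function(tc, n_points = 200, max_degree = 6) {
  stopifnot(inherits(tc, "grn_timecourse"))
  if (dim(tc$values)[3] != 1) {
    stop_bad("interpolation expects a single replicate; call average_replicates() first")
  }
  n_points <- check_count(n_points, "n_points", min = 2)
  max_degree <- check_count(max_degree, "max_degree", min = 2)
  n_t <- length(tc$times)
  if (n_t < max_degree + 1) {
    stop_bad("need at least max_degree + 1 = %d timepoints, got %d", max_degree + 1, n_t)
  }
  t_min <- min(tc$times)
  t_range <- diff(range(tc$times))
  u <- (tc$times - t_min) / t_range
  grid <- seq(0, 1, length.out = n_points)
  degrees <- 2:max_degree

  n <- length(tc$gene_names)
  vals <- matrix(NA_real_, n, n_points)
  devs <- matrix(NA_real_, n, n_points)
  fit_degree <- integer(n)
  y_all <- tc$values[, , 1, drop = FALSE]
  for (g in seq_len(n)) {
    y <- y_all[g, , 1]
    best <- NULL
    for (d in degrees) {
      f <- polyfit_loo(u, y, d)
      if (is.null(best) || f$loo < best$loo - 1e-12) best <- f
    }
    fit_degree[g] <- best$degree
    co <- best$coef
    vals[g, ] <- polyval(co, grid)
    dcoef <- co[-1] * seq_len(length(co) - 1)
    devs[g, ] <- polyval(dcoef, grid) / t_range
  }
  grn_interp(vals, devs, seq(t_min, t_min + t_range, length.out = n_points),
             fit_degree, tc$gene_names)
}

# least-squares polynomial fit of given degree with leave-one-out error
polyfit_loo <- function(u, y, degree) {
  X <- outer(u, 0:degree, `^`)
  qrx <- qr(X)
  coef <- qr.coef(qrx, y)
  coef[is.na(coef)] <- 0
  resid <- y - drop(X %*% coef)
  q <- qr.Q(qrx)
  h <- rowSums(q[, seq_len(qrx$rank), drop = FALSE]^2)
  h <- pmin(h, 1 - 1e-10)
  list(degree = degree, coef = coef, loo = mean((resid / (1 - h))^2))
}

polyval <- function(coef, x) {
  # coefficients in increasing power order
  out <- rep(0, length(x))
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' Derivative matrix of an interpolated series
#'
#' Returns the analytic derivative of the fitted per-gene polynomials, as a
#' genes x timepoints matrix in expression/time units. (For series built by
#' other means, central finite differences on the dense grid would be the
#' fallback; the polynomial backend always carries analytic derivatives.)
#'
#' @param series a [grn_interp()].
#' @return numeric matrix, same shape as `series$values`.
#' @export
estimate_derivatives <- function(series) {
  stopifnot(inherits(series, "grn_interp"))
  series$derivatives
}
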