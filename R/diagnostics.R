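# Trajectory-distance analysis, contraction-rate estimation, and spectral
# time series of the evolving weight matrix.

#' Euclidean distance between two simulated trajectories
#'
#' Pointwise Euclidean norm of the difference between the flattened states of
#' two simulations on the same time grid, optionally measured in a
#' transformed metric (the theta-weighted norm).  In a contracting system
#' this series shrinks to zero; in the certificate's metric it is
#' non-increasing even when the identity-metric series transiently rises.
#'
#' @param a,b [simulate_network()] results with matching grids and dimensions.
#' @param metric Optional [contraction_metric()] on the flattened state.
#' @return Object of class `distance_series`: a list with `times` and
#'   `distances`.
#' @export
trajectory_distance <- function(a, b, metric = NULL) {
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 1e-12)) {
    stop("trajectories are on different time grids", call. = FALSE)
  }
  if (ncol(a$states) != ncol(b$states)) {
    stop("trajectories have different state dimensions", call. = FALSE)
  }
  diff <- a$states - b$states
  if (!is.null(metric)) {
    if (!inherits(metric, "contraction_metric")) {
      stop("'metric' must be a contraction_metric", call. = FALSE)
    }
    if (nrow(metric$theta) != ncol(diff)) {
      stop("metric dimension does not match state dimension", call. = FALSE)
    }
    diff <- diff %*% t(metric$theta)
  }
  structure(list(times = a$times, distances = sqrt(rowSums(diff^2))),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d points, %.4g -> %.4g\n",
              length(x$times), x$distances[1],
              x$distances[length(x$distances)]))
  invisible(x)
}

#' Estimate the contraction rate from a distance series
#'
#' Fits log-distance against time by ordinary least squares on a window and
#' returns the negated slope: for a cleanly contracting system the distance
#' decays as \eqn{d_0 e^{-ct}} and the fit recovers `c` with
#' \eqn{r^2 \approx 1}.  Distances must be strictly positive on the window.
#'
#' @param d A [trajectory_distance()] result.
#' @param fit_window Length-2 numeric, the time interval to fit on
#'   (default: the full series).
#' @return List with `rate` (positive = contracting) and `r_squared`.
#' @export
estimate_contraction_rate <- function(d, fit_window = range(d$times)) {
  sel <- d$times >= fit_window[1] & d$times <= fit_window[2]
  if (sum(sel) < 3) stop("fit window contains fewer than 3 points",
                         call. = FALSE)
  dist <- d$distances[sel]
  if (any(dist <= 0)) {
    stop("distance is zero (or negative) inside the fit window; ",
         "log-linear fit is degenerate", call. = FALSE)
  }
  tt <- d$times[sel]
  fit <- stats::lm.fit(cbind(1, tt), log(dist))
  slope <- fit$coefficients[2]
  res <- fit$residuals
  tot <- sum((log(dist) - mean(log(dist)))^2)
  r2 <- if (tot == 0) {
    # constant series: slope 0 fits exactly
    1.0
  } else {
    1 - sum(res^2) / tot
  }
  list(rate = -unname(slope), r_squared = r2)
}

#' Spectral time series of the evolving weight matrix
#'
#' For each recorded time of a plastic-network simulation, computes the
#' spectral norm of the full weight matrix \eqn{\|W\|_2}, the spectral norm of
#' its antisymmetric part (decaying to zero means the matrix becomes
#' symmetric), the largest eigenvalue of its symmetric part (which must stay
#' below the neurons' leak rate for contraction), and a theoretical upper
#' bound for the latter.
#'
#' The default bound is \eqn{\lambda_{\max}(\mathrm{sym}\,W(0))
#' e^{-\int_0^t \gamma}}.  It is implementation-derived but provable for the
#' admissible learning-rate matrices: entrywise-positive PSD `K` makes the
#' correlational drive \eqn{-K \circ x x^T} negative semi-definite (Schur
#' product of PSD matrices), so the symmetric part's largest eigenvalue is
#' dominated by pure forgetting.
#'
#' @param result A plastic [simulate_network()] result.
#' @param model A [neural_model()] (for dimensions; unused otherwise).
#' @param plasticity The [plasticity_spec()] of the run (for `gamma`).
#' @param bound_fn Optional replacement bound: `function(t, trace0)` where
#'   `trace0` holds `lambda_max_sym0` and `gamma`.
#' @return Object of class `spectral_trace`: `times`, `spec_norm_w`,
#'   `spec_norm_antisym`, `lambda_max_sym`, `bound`.
#' @export
weight_spectral_trace <- function(result, model, plasticity,
                                  bound_fn = NULL) {
  if (result$static) {
    stop("spectral trace requires a plastic-network result with weight ",
         "trajectories", call. = FALSE)
  }
  n <- result$n
  nt <- length(result$times)
  spec_w <- spec_anti <- lam_sym <- numeric(nt)
  for (i in seq_len(nt)) {
    w <- matrix(result$states[i, -seq_len(n)], n, n, byrow = TRUE)
    spec_w[i] <- norm(w, "2")
    spec_anti[i] <- norm(antisym_part(w), "2")
    lam_sym[i] <- max(eigen(sym_part(w), symmetric = TRUE,
                            only.values = TRUE)$values)
  }
  gamma_int <- .cumulative_gamma(plasticity, result$times)
  if (is.null(bound_fn)) {
    bound <- lam_sym[1] * exp(-gamma_int)
  } else {
    trace0 <- list(lambda_max_sym0 = lam_sym[1], gamma = plasticity$gamma)
    bound <- vapply(result$times, bound_fn, numeric(1), trace0 = trace0)
  }
  structure(list(times = result$times, spec_norm_w = spec_w,
                 spec_norm_antisym = spec_anti, lambda_max_sym = lam_sym,
                 bound = bound),
            class = "spectral_trace")
}

# integral of gamma from 0 to each time (exact for constant gamma,
# trapezoidal otherwise)
.cumulative_gamma <- function(plasticity, times) {
  if (!is.na(plasticity$gamma_constant)) {
    return(plasticity$gamma_constant * times)
  }
  g <- vapply(times, plasticity$gamma, numeric(1))
  c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(times)))
}

#' @export
print.spectral_trace <- function(x, ...) {
  cat(sprintf(
    "<spectral_trace> %d points; ||antisym W||: %.4g -> %.4g; lambda_max(sym W): %.4g -> %.4g\n",
    length(x$times), x$spec_norm_antisym[1],
    x$spec_norm_antisym[length(x$times)], x$lambda_max_sym[1],
    x$lambda_max_sym[length(x$times)]))
  invisible(x)
}

#' Check the symmetric-part eigenvalue prerequisite along a run
#'
#' A prerequisite for overall contraction is that the largest eigenvalue of
#' the symmetric part of `W(t)` stay at or below the neurons' leak rate
#' \eqn{\min_i \beta_i}.  Checks this pointwise after a burn-in (transients
#' from a randomly seeded `W(0)` may start above the leak rate and are driven
#' down by the plasticity).
#'
#' @param trace A [weight_spectral_trace()].
#' @param model A [neural_model()] supplying the leak rates.
#' @param burn_in Fraction of the run excluded from the check (default 0.1).
#' @return List with `ok` (logical), `margins` (per-time-point
#'   \eqn{\min_i \beta_i - \lambda_{\max}(\mathrm{sym}\,W(t))}) and `times`.
#' @export
bound_check <- function(trace, model, burn_in = 0.1) {
  margins <- min(model$beta) - trace$lambda_max_sym
  t_min <- burn_in * max(trace$times)
  ok <- all(margins[trace$times >= t_min] >= 0)
  list(ok = ok, margins = margins, times = trace$times)
}
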