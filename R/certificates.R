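# Stability certificates: hypotheses of the plasticity-based contraction
# theorem, the sparsity inequality, symmetric-part tests for static weights,
# E-I balance block-cancellation, the discrete-time echo-state check, and the
# time-varying counterexample showing eigenvalues alone do not determine
# stability.

#' Container for the outcome of a stability certificate
#'
#' A certificate passes only if every named hypothesis check passed and every
#' margin is strictly positive; the constructor enforces that conjunction.
#'
#' @param certificate_name Label of the certificate.
#' @param margins Named numeric vector of per-neuron / per-condition margins
#'   (positive = satisfied with room to spare).
#' @param details Named list of diagnostics (eigenvalues, bounds, metric
#'   used, ...).
#' @param assumptions_checked Named logical vector of hypothesis checks.
#' @return Object of class `certificate_report` with an additional `passed`
#'   field.
#' @export
certificate_report <- function(certificate_name, margins = numeric(0),
                               details = list(),
                               assumptions_checked = logical(0)) {
  passed <- all(assumptions_checked) && all(margins > 0) &&
    !anyNA(margins) && !anyNA(assumptions_checked)
  structure(list(certificate = certificate_name,
                 passed = isTRUE(passed),
                 margins = margins,
                 details = details,
                 assumptions_checked = assumptions_checked),
            class = "certificate_report")
}

#' @export
print.certificate_report <- function(x, ...) {
  cat(sprintf("<certificate_report> %s: %s\n", x$certificate,
              if (x$passed) "PASSED" else "FAILED"))
  if (length(x$assumptions_checked)) {
    for (nm in names(x$assumptions_checked)) {
      cat(sprintf("  [%s] %s\n",
                  if (x$assumptions_checked[[nm]]) "ok" else "FAIL", nm))
    }
  }
  if (length(x$margins)) {
    cat(sprintf("  margins: min %.4g (n = %d)\n", min(x$margins),
                length(x$margins)))
  }
  invisible(x)
}

#' Check the hypotheses on the learning-rate matrix
#'
#' The contraction theorem for the correlational plasticity requires the
#' learning-rate matrix `K` to be symmetric, entrywise (strictly) positive,
#' and positive semi-definite.  The equal-rate case `K = k * ones` satisfies
#' all three (a rank-1 PSD matrix).  Failures are reported in the
#' certificate, never raised.
#'
#' @param plasticity A [plasticity_spec()].
#' @return A [certificate_report()] with the three named checks.
#' @examples
#' check_plasticity_hypotheses(plasticity_spec(k = 1, n = 4))$passed # TRUE
#' @export
check_plasticity_hypotheses <- function(plasticity) {
  k <- plasticity$k_matrix
  sym_ok <- isTRUE(all.equal(k, t(k), tolerance = 1e-10))
  pos_ok <- all(k > 0)
  ev <- eigen((k + t(k)) / 2, symmetric = TRUE, only.values = TRUE)$values
  psd_ok <- min(ev) >= -1e-10 * max(1, norm(k, "2"))
  certificate_report(
    "plasticity_hypotheses",
    details = list(eigenvalues = ev, min_entry = min(k)),
    assumptions_checked = c(symmetric = sym_ok,
                            entrywise_positive = pos_ok,
                            positive_semidefinite = psd_ok))
}

# Diagonal metric for the combined system derived from K: identity on the
# neural block, 1/sqrt(k_ij) on synaptic coordinate W_ij.  This rescaling
# makes the neural->synaptic and synaptic->neural Jacobian cross-blocks
# (nearly) equal-and-opposite pairs; its adequacy is verified numerically by
# the certificate, not assumed.
plasticity_metric_scales <- function(plasticity) {
  k <- plasticity$k_matrix
  n <- nrow(k)
  if (any(k <= 0)) {
    stop("the K-derived metric requires entrywise-positive K", call. = FALSE)
  }
  c(rep(1, n), as.vector(t(1 / sqrt(k))))
}

# Matrix-free matvec of sym(theta J theta^{-1}) for the combined system at a
# given state, with theta the K-derived diagonal metric.  s = sqrt(K).
.make_sym_jacobian_matvec <- function(state, model, plasticity, t = 0) {
  n <- state$n
  x <- state$x
  w <- state$w
  s <- sqrt(plasticity$k_matrix)
  gam <- plasticity$gamma(t)
  rx <- model$act(x)
  drx <- model$act_deriv(x)
  a_xx <- diag(model$leak_deriv(x), n, n) + w * rep(drx, each = n)
  ix <- seq_len(n)
  function(v) {
    vx <- v[ix]
    vw <- matrix(v[-ix], n, n, byrow = TRUE)
    # J' v
    jx <- as.vector(a_xx %*% vx) + as.vector((s * vw) %*% rx)
    jw <- -s * (tcrossprod(vx, x) + tcrossprod(x, vx)) - gam * vw
    # t(J') v
    sv <- s * vw
    tx <- as.vector(crossprod(a_xx, vx)) -
      as.vector(sv %*% x) - as.vector(crossprod(sv, x))
    tw <- s * tcrossprod(vx, rx) - gam * vw
    0.5 * c(jx + tx, as.vector(t(jw + tw)))
  }
}

#' Contraction certificate for the correlational-plasticity network
#'
#' Certifies contraction of the combined neural + synaptic system under the
#' correlational plasticity rule, for the linear-rate model (identity
#' activation).  Hypotheses checked: `K` symmetric / entrywise positive /
#' PSD, identity activation, and `gamma > 0` on the horizon (with
#' `gamma = 0` the synaptic block of the Jacobian loses its `-gamma I`
#' negativity and the certificate fails).  The conclusion is verified
#' numerically: an input-free test trajectory is simulated and
#' \eqn{\mu_2} of the metric-transformed Jacobian is evaluated at sampled
#' times; the certificate passes if it is strictly negative on the tail of
#' the trajectory (after `burn_in`).  The metric is the K-derived diagonal
#' rescaling (reported as `"K-rescaled (implementation choice)"`); transient
#' positivity during the burn-in is expected whenever
#' \eqn{\lambda_{\max}(\mathrm{sym}\,W(0))} exceeds the leak rate.
#'
#' @param model A [neural_model()]; must use the identity activation.
#' @param plasticity A [plasticity_spec()].
#' @param init Optional [network_state()] to start the test trajectory from
#'   (default: random uniform on `[-1, 1]` from `seed`).
#' @param horizon Length of the test trajectory (default 10 time units).
#' @param n_samples Number of Jacobian evaluation times (default 50).
#' @param burn_in Fraction of the horizon excluded from the negativity check
#'   (default 0.5).
#' @param dt Integration step for the test trajectory.
#' @param seed Seed for the default initial state.
#' @return A [certificate_report()].  `margins` are \eqn{-\mu_2} at the
#'   sampled tail times; `details` carry the full \eqn{\mu_2} series, the
#'   sample times and the metric description.
#' @export
hebbian_contraction_certificate <- function(model, plasticity, init = NULL,
                                            horizon = 10, n_samples = 50,
                                            burn_in = 0.5, dt = 1e-2,
                                            seed = 1) {
  hyp <- check_plasticity_hypotheses(plasticity)
  checks <- hyp$assumptions_checked
  checks["identity_activation"] <- model$activation == "identity"
  gam <- vapply(seq(0, horizon, length.out = 25), plasticity$gamma,
                numeric(1))
  checks["gamma_positive"] <- all(gam > 0)
  if (!all(checks)) {
    return(certificate_report(
      "hebbian_contraction",
      details = list(metric = "K-rescaled (implementation choice)",
                     failed_checks = names(checks)[!checks]),
      assumptions_checked = checks))
  }
  n <- model$n
  if (is.null(init)) init <- random_initial_state(n, seed)
  protocol <- simulation_protocol(t_end = horizon, dt = dt, seed = seed,
                                  record_every = max(
                                    1L, as.integer(round(horizon / dt /
                                                           n_samples))))
  res <- simulate_network(model, plasticity, init, protocol)
  scales <- plasticity_metric_scales(plasticity)
  dim_tot <- n + n^2
  mu_series <- vapply(seq_along(res$times), function(i) {
    st <- unflatten_state(res$states[i, ], n)
    tt <- res$times[i]
    if (dim_tot <= 1500) {
      jac <- combined_jacobian(st, model, plasticity, tt)
      jac_m <- jac * tcrossprod(scales, 1 / scales)
      mu2(jac_m)
    } else {
      mv <- .make_sym_jacobian_matvec(st, model, plasticity, tt)
      .lanczos_lambda_max(mv, dim_tot)
    }
  }, numeric(1))
  tail_sel <- res$times >= burn_in * horizon
  margins <- -mu_series[tail_sel]
  names(margins) <- sprintf("t=%.3g", res$times[tail_sel])
  certificate_report(
    "hebbian_contraction",
    margins = margins,
    details = list(metric = "K-rescaled (implementation choice)",
                   mu2_series = mu_series, times = res$times,
                   burn_in = burn_in, horizon = horizon),
    assumptions_checked = checks)
}

#' Sparsity profile of a network
#'
#' Per-neuron afferent synapse counts `p_i`, plastic-afferent fractions
#' `alpha_i` in `[0, 1]`, and the maximum synaptic efficiency
#' `w_max = max |w_ij|`.
#'
#' @param p_per_neuron Nonnegative integer vector (scalar recycled).
#' @param alpha_per_neuron Fractions in `[0, 1]` (scalar recycled).
#' @param w_max Nonnegative scalar.
#' @param n Number of neurons (needed when both vectors are scalar).
#' @return Object of class `sparsity_profile`.
#' @export
sparsity_profile <- function(p_per_neuron, alpha_per_neuron = 0, w_max,
                             n = max(length(p_per_neuron),
                                     length(alpha_per_neuron))) {
  p <- rep_len(as.numeric(p_per_neuron), n)
  alpha <- rep_len(as.numeric(alpha_per_neuron), n)
  if (any(p < 0) || any(p != round(p))) {
    stop("'p_per_neuron' must be nonnegative integers", call. = FALSE)
  }
  if (any(alpha < 0 | alpha > 1)) {
    stop("'alpha_per_neuron' must lie in [0, 1]", call. = FALSE)
  }
  if (w_max < 0) stop("'w_max' must be >= 0", call. = FALSE)
  structure(list(p_per_neuron = p, alpha_per_neuron = alpha,
                 w_max = as.numeric(w_max), n = n),
            class = "sparsity_profile")
}

#' Sparsity-based contraction certificate
#'
#' Checks, per neuron, the sparsity inequality
#' \deqn{p_i (g_{\max} w_{\max} + \alpha_i r_{\max}) < \beta_i,}
#' which guarantees overall contraction when every plastic synapse carries a
#' forgetting term.  `margins[i] = beta_i - p_i (g_max * w_max + alpha_i *
#' r_max)`; the certificate passes iff all margins are strictly positive.
#' `p_i = 0` is the trivially contracting disconnected case.  The derivation
#' assumes a bounded activation wherever plastic synapses are present, so
#' `alpha_i > 0` with unbounded `r_max` is a precondition error.
#'
#' @param model A [neural_model()] supplying `beta`, `g_max`, `r_max`.
#' @param sparsity A [sparsity_profile()].
#' @return A [certificate_report()] with per-neuron margins.
#' @examples
#' m <- neural_model(1, activation = "tanh")
#' sparsity_certificate(m, sparsity_profile(1, 0.5, w_max = 0.1))$margins
#' @export
sparsity_certificate <- function(model, sparsity) {
  if (any(sparsity$alpha_per_neuron > 0) && !is.finite(model$r_max)) {
    stop("sparsity certificate assumes a bounded activation (finite r_max) ",
         "whenever any alpha_i > 0; use a saturating activation or set ",
         "alpha = 0", call. = FALSE)
  }
  n <- sparsity$n
  beta <- rep_len(model$beta, n)
  load <- sparsity$p_per_neuron *
    (model$g_max * sparsity$w_max +
       sparsity$alpha_per_neuron * ifelse(sparsity$alpha_per_neuron > 0,
                                          model$r_max, 0))
  margins <- beta - load
  names(margins) <- sprintf("neuron_%d", seq_len(n))
  certificate_report(
    "sparsity",
    margins = margins,
    details = list(g_max = model$g_max, r_max = model$r_max,
                   w_max = sparsity$w_max),
    assumptions_checked = c(
      bounded_activation_if_plastic =
        all(sparsity$alpha_per_neuron == 0) || is.finite(model$r_max)))
}

#' Symmetric-part eigenvalue certificate for static weights
#'
#' For a network with frozen weights, contraction can be assessed from the
#' eigenvalues of the symmetric part of `W`: the certificate passes iff
#' \eqn{g_{\max} \lambda_{\max}(\mathrm{sym}\,W) < \min_i \beta_i}, with
#' margin \eqn{\min_i \beta_i - g_{\max} \lambda_{\max}(\mathrm{sym}\,W)}.
#' An antisymmetric weight matrix contributes nothing to the symmetric part
#' and passes with margin equal to the leak rate.
#'
#' @param w Square weight matrix.
#' @param model A [neural_model()].
#' @return A [certificate_report()] with a single margin.
#' @export
static_symmetric_part_certificate <- function(w, model) {
  .check_square(w, "w")
  lam <- max(eigen(sym_part(w), symmetric = TRUE, only.values = TRUE)$values)
  margin <- min(model$beta) - model$g_max * lam
  certificate_report(
    "static_symmetric_part",
    margins = c(symmetric_part = margin),
    details = list(lambda_max_sym = lam, g_max = model$g_max,
                   beta_min = min(model$beta)),
    assumptions_checked = c(finite_weights = all(is.finite(w))))
}

#' Excitatory/inhibitory partition of a network
#'
#' Disjoint index sets covering all neurons, defining the two-population
#' block structure of the weight matrix.
#'
#' @param excitatory_indices,inhibitory_indices Integer index vectors.
#' @param n Total number of neurons.
#' @return Object of class `ei_partition`.
#' @export
ei_partition <- function(excitatory_indices, inhibitory_indices, n) {
  e <- as.integer(excitatory_indices)
  i <- as.integer(inhibitory_indices)
  if (length(intersect(e, i)) > 0 ||
      !setequal(union(e, i), seq_len(n))) {
    stop("partition must cover 1..n with no overlap", call. = FALSE)
  }
  structure(list(excitatory = e, inhibitory = i, n = as.integer(n)),
            class = "ei_partition")
}

#' E-I balance certificate
#'
#' Balanced cross-population connections cannot destabilize a static
#' network: when excitatory-to-inhibitory weights equal the negated
#' transpose of the inhibitory-to-excitatory weights, the cross blocks
#' cancel identically in the symmetric part of `W`, so stability is decided
#' by the within-population weights alone -- regardless of the cross-block
#' amplitude.  The certificate (a) checks the sign conventions (E-to-I block
#' nonnegative, I-to-E block nonpositive), (b) checks the cancellation
#' residual \eqn{\|W_{EI} + W_{IE}^T\|_2 \le \mathrm{tol} (\|W_{EI}\|_2 +
#' \|W_{IE}\|_2)} (exact balance at `tolerance = 0`, "statistical" balance
#' otherwise), and (c) applies [static_symmetric_part_certificate()] to the
#' full matrix, in which any residual is automatically accounted for.
#'
#' @param w Square weight matrix.
#' @param partition An [ei_partition()].
#' @param model A [neural_model()].
#' @param tolerance Relative cancellation residual allowed (default 0.05).
#' @return A [certificate_report()].
#' @export
ei_balance_certificate <- function(w, partition, model, tolerance = 0.05) {
  .check_square(w, "w")
  if (!inherits(partition, "ei_partition") || partition$n != nrow(w)) {
    stop("'partition' must be an ei_partition covering the matrix",
         call. = FALSE)
  }
  e <- partition$excitatory
  i <- partition$inhibitory
  w_ie <- w[i, e, drop = FALSE]  # E -> I connections
  w_ei <- w[e, i, drop = FALSE]  # I -> E connections
  sign_ok <- all(w_ie >= 0) && all(w_ei <= 0)
  # spectral norm: the residual's contribution to lambda_max(sym W) is what
  # matters for stability, and statistically balanced blocks have a small
  # spectral residual even when entrywise differences are O(1)
  res <- norm(w_ei + t(w_ie), "2")
  scale <- norm(w_ei, "2") + norm(w_ie, "2")
  balance_ok <- if (scale == 0) TRUE else res <= tolerance * scale
  static <- static_symmetric_part_certificate(w, model)
  certificate_report(
    "ei_balance",
    margins = static$margins,
    details = list(cancellation_residual = res,
                   cancellation_scale = scale,
                   relative_residual = if (scale == 0) 0 else res / scale,
                   tolerance = tolerance,
                   lambda_max_sym = static$details$lambda_max_sym),
    assumptions_checked = c(dale_signs = sign_ok,
                            cross_block_balance = balance_ok,
                            finite_weights = all(is.finite(w))))
}

#' Echo-state (discrete-time) contraction check
#'
#' For the discrete-time update \eqn{x^+ = r(Wx + u)} with activation gain at
#' most `g_max`, the map is a contraction when \eqn{g_{\max}
#' \sigma_{\max}(W) < 1}; margin \eqn{1 - g_{\max} \sigma_{\max}(W)}.  This
#' is the standard sufficient condition under which an echo state network
#' forgets its initial state, and places such networks inside the contracting
#' family.
#'
#' @param w Square weight matrix.
#' @param g_max Maximum activation gain (default 1).
#' @return A [certificate_report()].
#' @export
esn_discrete_contraction_check <- function(w, g_max = 1) {
  .check_square(w, "w")
  sigma <- norm(w, "2")
  certificate_report(
    "esn_discrete_contraction",
    margins = c(spectral = 1 - g_max * sigma),
    details = list(sigma_max = sigma, g_max = g_max),
    assumptions_checked = c(positive_gain = g_max > 0))
}

#' Why eigenvalues do not determine time-varying stability
#'
#' The linear time-varying system
#' \deqn{\dot x = -x + e^{2t} y, \qquad \dot y = -y}
#' has a triangular system matrix whose eigenvalues are constant at
#' \eqn{(-1, -1)} for all times, yet from \eqn{(x, y)(0) = (0, 1)} the
#' solution is \eqn{y(t) = e^{-t}}, \eqn{x(t) = \sinh(t)}: unstable along
#' `x`.  The symmetric part tells the truth: \eqn{\mu_2(A(t)) = -1 +
#' e^{2t}/2} turns positive at \eqn{t = \ln(2)/2}.  The demo returns the
#' sampled eigenvalues, the sampled \eqn{\mu_2} series with its numerically
#' located zero crossing, the closed-form trajectory, and an RK4-integrated
#' trajectory for comparison.
#'
#' @param t_end Horizon (default 2).
#' @param dt Integration step (default 1e-4).
#' @param n_samples Number of sample times for eigenvalues and \eqn{\mu_2}.
#' @return List with `sample_times`, `eigenvalues` (matrix, one row per
#'   sample time), `mu2_values`, `mu2_zero_crossing`, `times`, `closed_form`
#'   (matrix `x, y`), `integrated` (matrix `x, y`), `max_abs_error`.
#' @export
eigenvalue_test_insufficiency_demo <- function(t_end = 2, dt = 1e-4,
                                               n_samples = 41) {
  sys <- counterexample_system()
  sample_times <- seq(0, t_end, length.out = n_samples)
  eigs <- t(vapply(sample_times,
                   function(t) sort(Re(eigen(sys$A(t),
                                             only.values = TRUE)$values)),
                   numeric(2)))
  mu2_values <- vapply(sample_times, function(t) mu2(sys$A(t)), numeric(1))
  crossing <- stats::uniroot(function(t) mu2(sys$A(t)),
                             interval = c(0, t_end), tol = 1e-12)$root
  out <- rk4_integrate(sys$rhs, c(0, 1), t_end, dt,
                       record_every = max(1L, as.integer(round(0.01 / dt))))
  closed <- cbind(x = sys$solution_x(out$times, x0 = 0, y0 = 1),
                  y = sys$solution_y(out$times, y0 = 1))
  colnames(out$states) <- c("x", "y")
  list(sample_times = sample_times, eigenvalues = eigs,
       mu2_values = mu2_values, mu2_zero_crossing = crossing,
       times = out$times, closed_form = closed, integrated = out$states,
       max_abs_error = max(abs(out$states - closed)))
}
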