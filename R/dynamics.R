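# Right-hand sides and Jacobian of the combined neural + synaptic system.
#
# Neural dynamics:   xdot_i = h(x_i) + sum_j W_ij r(x_j) + u_i(t)
# Synaptic dynamics: Wdot_ij = -k_ij x_i x_j - gamma(t) W_ij
#
# x_i is the deviation of neuron i from its baseline rate (may be negative);
# self-feedback lives in the leak h, so fixtures keep diag(W) = 0.  The
# combined state is the (n + n^2)-vector [x; rows of W, row-major].

.activations <- list(
  identity = list(f = function(x) x, df = function(x) rep(1, length(x)),
                  g_max = 1, r_max = Inf),
  tanh = list(f = tanh, df = function(x) 1 / cosh(x)^2,
              g_max = 1, r_max = 1)
)

#' Specify the single-neuron model
#'
#' Defines the leak and activation of every neuron plus the derived scalars
#' used by the certificates: the isolated-neuron contraction rates
#' \eqn{\beta_i = -\max_x h_i'(x)} (the "leak rate", the stability budget each
#' neuron brings), the maximum activation gain \eqn{g_{\max} = \max |r'|}, and
#' the maximum activation magnitude \eqn{r_{\max} = \max |r|} (infinite for
#' the identity activation).
#'
#' The leak is linear, \eqn{h_i(x) = -\beta_i x}, the standard choice, with
#' all time constants equal to one when `beta = 1`.
#'
#' @param n Number of neurons.
#' @param activation `"identity"` (linear rate model) or `"tanh"` (saturating).
#' @param beta Positive leak rate(s); scalar or length-`n` vector.
#' @return An object of class `neural_model` with components `n`, `activation`,
#'   `act`, `act_deriv`, `leak`, `leak_deriv`, `beta`, `g_max`, `r_max`.
#' @examples
#' neural_model(10)
#' neural_model(10, activation = "tanh")
#' @export
neural_model <- function(n, activation = c("identity", "tanh"), beta = 1) {
  activation <- match.arg(activation)
  n <- as.integer(n)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  beta <- rep_len(as.numeric(beta), n)
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("'beta' must be strictly positive and finite", call. = FALSE)
  }
  act <- .activations[[activation]]
  structure(list(
    n = n,
    activation = activation,
    act = act$f,
    act_deriv = act$df,
    leak = function(x) -beta * x,
    leak_deriv = function(x) -beta,
    beta = beta,
    g_max = act$g_max,
    r_max = act$r_max
  ), class = "neural_model")
}

#' @export
print.neural_model <- function(x, ...) {
  cat(sprintf("<neural_model> n = %d, activation = %s, beta in [%g, %g]\n",
              x$n, x$activation, min(x$beta), max(x$beta)))
  invisible(x)
}

#' Specify the correlational plasticity rule
#'
#' The synaptic dynamics are \eqn{\dot W_{ij} = -k_{ij} x_i x_j - \gamma(t)
#' W_{ij}}: Hebbian for inhibitory synapses (correlated activity strengthens
#' inhibition) and anti-Hebbian for excitatory ones, plus exponential
#' forgetting at rate \eqn{\gamma(t)}.  The contraction theorem for this rule
#' requires `K` symmetric, entrywise positive and positive semi-definite (see
#' [check_plasticity_hypotheses()]); the constructor stores `K` without
#' enforcing those so that failing matrices can be fed to the certificate.
#'
#' @param k Learning rates: scalar (expanded to `k * ones(n, n)`, the
#'   equal-rate case) or a full `n x n` matrix.
#' @param n Number of neurons; required when `k` is scalar.
#' @param gamma Forgetting rate: positive scalar or a function of time.
#' @return Object of class `plasticity_spec` with components `k_matrix`,
#'   `gamma` (function of t) and `gamma_constant` (scalar or NA).
#' @examples
#' plasticity_spec(k = 1, n = 5)
#' @export
plasticity_spec <- function(k, n = NULL, gamma = 1) {
  if (is.matrix(k)) {
    .check_square(k, "k")
    k_matrix <- k
  } else {
    if (is.null(n)) stop("'n' is required when 'k' is scalar", call. = FALSE)
    k_matrix <- matrix(as.numeric(k), n, n)
  }
  if (is.function(gamma)) {
    gamma_fn <- gamma
    gamma_constant <- NA_real_
  } else {
    g <- as.numeric(gamma)
    if (length(g) != 1 || !is.finite(g)) {
      stop("'gamma' must be a finite scalar or a function of time",
           call. = FALSE)
    }
    gamma_fn <- function(t) g
    gamma_constant <- g
  }
  structure(list(k_matrix = k_matrix, gamma = gamma_fn,
                 gamma_constant = gamma_constant),
            class = "plasticity_spec")
}

#' @export
print.plasticity_spec <- function(x, ...) {
  g <- if (is.na(x$gamma_constant)) "function(t)" else
    format(x$gamma_constant)
  cat(sprintf("<plasticity_spec> n = %d, gamma = %s\n",
              nrow(x$k_matrix), g))
  invisible(x)
}

#' Network state: activations plus weight matrix
#'
#' Bundles the length-`n` activation vector `x` and the `n x n` weight matrix
#' `w` (positive entries excitatory, negative inhibitory) at one time point.
#' The flattened layout is `[x; rows of w, row-major]`, total length
#' `n + n^2`; [flatten_state()] and [unflatten_state()] enforce the layout.
#'
#' @param x Numeric vector of activations.
#' @param w Square numeric weight matrix with `nrow(w) == length(x)`.
#' @return Object of class `network_state`.
#' @export
network_state <- function(x, w) {
  x <- as.numeric(x)
  .check_square(w, "w")
  if (nrow(w) != length(x)) {
    stop("'w' must be length(x) x length(x)", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("'x' contains non-finite entries", call. = FALSE)
  structure(list(x = x, w = w, n = length(x)), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> n = %d (flattened length %d)\n",
              x$n, x$n + x$n^2))
  invisible(x)
}

#' @rdname network_state
#' @param state A `network_state`.
#' @export
flatten_state <- function(state) {
  c(state$x, as.vector(t(state$w)))
}

#' @rdname network_state
#' @param v Flattened state vector of length `n + n^2`.
#' @param n Number of neurons.
#' @export
unflatten_state <- function(v, n) {
  if (length(v) != n + n^2) {
    stop(sprintf("flattened state must have length n + n^2 = %d, got %d",
                 n + n^2, length(v)), call. = FALSE)
  }
  network_state(v[seq_len(n)], matrix(v[-seq_len(n)], n, n, byrow = TRUE))
}

#' Neural right-hand side
#'
#' Evaluates \eqn{\dot x_i = h(x_i) + \sum_j W_{ij} r(x_j) + u_i} for the
#' current state.  With the identity activation this is the linear-rate model;
#' with `tanh` it is the saturating variant.
#'
#' @param state A [network_state()].
#' @param model A [neural_model()].
#' @param input_value Numeric input vector `u` (scalar recycled; default 0).
#' @return Numeric vector `dx/dt` of length `n`.
#' @export
neural_rhs <- function(state, model, input_value = 0) {
  n <- model$n
  if (state$n != n) stop("state/model dimension mismatch", call. = FALSE)
  u <- rep_len(as.numeric(input_value), n)
  model$leak(state$x) + as.vector(state$w %*% model$act(state$x)) + u
}

#' Plasticity right-hand side
#'
#' Evaluates \eqn{\dot W = -K \circ (x x^T) - \gamma(t) W} (entrywise product
#' of the learning-rate matrix with the activity outer product, plus
#' forgetting).  When `K` is symmetric the correlational drive is a symmetric
#' matrix, which is what drives the weight matrix toward symmetry.
#'
#' @inheritParams neural_rhs
#' @param plasticity A [plasticity_spec()].
#' @param t Time (passed to `gamma`).
#' @return `n x n` matrix `dW/dt`.
#' @export
plasticity_rhs <- function(state, plasticity, t = 0) {
  if (nrow(plasticity$k_matrix) != state$n) {
    stop("state/plasticity dimension mismatch", call. = FALSE)
  }
  -plasticity$k_matrix * tcrossprod(state$x) - plasticity$gamma(t) * state$w
}

#' Predicted effect of the plasticity on synaptic efficiency
#'
#' For the correlational rule, the drive term changes the efficiency
#' \eqn{|w|} of a synapse according to the signs of the weight and of the
#' pre/post correlation: excitatory synapses between correlated neurons
#' weaken (anti-Hebbian), inhibitory synapses between correlated neurons
#' strengthen (Hebbian), and both reverse for anticorrelated pairs.  The
#' forgetting term is ignored.
#'
#' @param w_sign `"excitatory"` (w > 0) or `"inhibitory"` (w < 0).
#' @param correlation_sign `"correlated"` (x_i x_j > 0) or `"anticorrelated"`.
#' @return `"more_efficient"` or `"less_efficient"` (the sign of
#'   \eqn{\Delta |w|}).
#' @examples
#' classify_plasticity_effect("excitatory", "correlated")   # less_efficient
#' classify_plasticity_effect("inhibitory", "correlated")   # more_efficient
#' @export
classify_plasticity_effect <- function(
    w_sign = c("excitatory", "inhibitory"),
    correlation_sign = c("correlated", "anticorrelated")) {
  w_sign <- match.arg(w_sign)
  correlation_sign <- match.arg(correlation_sign)
  # d|w|/dt = sign(w) * (-k x_i x_j): negative for (+, +) and (-, -)
  sw <- if (w_sign == "excitatory") 1 else -1
  sc <- if (correlation_sign == "correlated") 1 else -1
  if (sw * sc > 0) "less_efficient" else "more_efficient"
}

#' Combined neural + synaptic right-hand side (flattened)
#'
#' Concatenates [neural_rhs()] with the row-major flattening of
#' [plasticity_rhs()], in the [network_state()] layout.  This is the vector
#' field of the single \eqn{(n + n^2)}-dimensional system whose contraction
#' the certificates assess.
#'
#' @inheritParams plasticity_rhs
#' @param model A [neural_model()].
#' @param input_value Input vector for the neural block.
#' @return Numeric vector of length `n + n^2`.
#' @export
combined_rhs <- function(state, model, plasticity, input_value = 0, t = 0) {
  c(neural_rhs(state, model, input_value),
    as.vector(t(plasticity_rhs(state, plasticity, t))))
}

#' Exact Jacobian of the combined system
#'
#' Returns the dense \eqn{(n+n^2) \times (n+n^2)} matrix of partial
#' derivatives of [combined_rhs()] with respect to the flattened state, with
#' blocks
#' \itemize{
#'   \item \eqn{\partial \dot x/\partial x = \mathrm{diag}(h'(x)) + W\,
#'     \mathrm{diag}(r'(x))}
#'   \item \eqn{\partial \dot x_i/\partial W_{ab} = \delta_{ia} r(x_b)}
#'   \item \eqn{\partial \dot W_{ij}/\partial x_a = -k_{ij}(\delta_{ia} x_j +
#'     \delta_{ja} x_i)}
#'   \item \eqn{\partial \dot W/\partial W = -\gamma(t) I}
#' }
#' Dense storage is quadratic in \eqn{n + n^2}; for large networks the
#' certificates use an equivalent matrix-free operator instead.
#'
#' @inheritParams combined_rhs
#' @return Square numeric matrix of size `n + n^2`.
#' @export
combined_jacobian <- function(state, model, plasticity, t = 0) {
  n <- state$n
  x <- state$x
  k <- plasticity$k_matrix
  rx <- model$act(x)
  drx <- model$act_deriv(x)
  dim_tot <- n + n^2
  jac <- matrix(0, dim_tot, dim_tot)
  ix <- seq_len(n)
  # d xdot / d x
  jac[ix, ix] <- diag(model$leak_deriv(x), n, n) +
    state$w * rep(drx, each = n)
  # d xdot_i / d W_ab = delta_{ia} r(x_b); row-major W columns
  jac[ix, -ix] <- kronecker(diag(n), matrix(rx, 1, n))
  # d Wdot_ij / d x_a = -k_ij (delta_{ia} x_j + delta_{ja} x_i)
  jwx <- matrix(0, n^2, n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * n + seq_len(n)        # row-major index of W_{i,1..n}
    block <- matrix(0, n, n)
    block[, i] <- block[, i] - k[i, ] * x   # delta_{ia} x_j term, a = i
    block <- block - diag(k[i, ] * x[i], n, n)  # delta_{ja} x_i term, a = j
    jwx[rows, ] <- block
  }
  jac[-ix, ix] <- jwx
  # d Wdot / d W
  iw <- (n + 1):dim_tot
  jac[cbind(iw, iw)] <- -plasticity$gamma(t)
  jac
}
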