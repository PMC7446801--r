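# Seeded generators for every network used in tests and figure
# reproduction.  All fixtures are bit-for-bit reproducible from their
# arguments and seed, and none of them disturb the caller's RNG state.

#' Random network with correlational plasticity
#'
#' The standard reproduction fixture: linear leak with unit rate, identity
#' activation, equal learning rates `K = k * ones`, constant forgetting
#' `gamma`, and initial activations and weights drawn uniformly on
#' `[-1, 1]` with a zero weight diagonal (self-feedback is carried by the
#' leak).
#'
#' @param n Number of neurons (`>= 2`).
#' @param k Learning rate (scalar, all synapses equal).
#' @param gamma Forgetting rate.
#' @param seed Integer seed.
#' @return List with `model` ([neural_model()]), `plasticity`
#'   ([plasticity_spec()]) and `state` ([network_state()]).
#' @examples
#' fx <- random_plastic_network(10, seed = 1)
#' range(fx$state$x)
#' @export
random_plastic_network <- function(n, k = 1, gamma = 1, seed = 0) {
  stopifnot(n >= 2)
  model <- neural_model(n, activation = "identity", beta = 1)
  plasticity <- plasticity_spec(k = k, n = n, gamma = gamma)
  state <- random_initial_state(n, seed)
  list(model = model, plasticity = plasticity, state = state)
}

#' Random sparse network with static weights
#'
#' Every neuron receives exactly `p` afferent synapses at uniformly random
#' presynaptic positions (excluding itself), with weights uniform on
#' `[-w_max, w_max]`.  All synapses are static (`alpha = 0`), so the
#' matching [sparsity_profile()] is `p_i = p`, `alpha_i = 0`, `w_max`.
#'
#' @param n Number of neurons.
#' @param p Afferent synapses per neuron, `0 <= p <= n - 1`.
#' @param w_max Maximum synaptic amplitude.
#' @param activation Activation passed to [neural_model()].
#' @param beta Leak rate(s).
#' @param seed Integer seed.
#' @return List with `model`, `sparsity` ([sparsity_profile()]) and `state`.
#' @export
sparse_static_network <- function(n, p, w_max, activation = "tanh",
                                  beta = 1, seed = 0) {
  if (p < 0 || p > n - 1) {
    stop("'p' must satisfy 0 <= p <= n - 1", call. = FALSE)
  }
  model <- neural_model(n, activation = activation, beta = beta)
  rng <- .local_rng(seed)
  w <- matrix(0, n, n)
  if (p > 0) {
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      pre <- others[rng$sample_int(n - 1, p)]
      w[i, pre] <- rng$runif(p, -w_max, w_max)
    }
  }
  x0 <- rng$runif(n, -1, 1)
  list(model = model,
       sparsity = sparsity_profile(p, 0, w_max = w_max, n = n),
       state = network_state(x0, w))
}

#' Two-neuron excitatory-inhibitory circuit
#'
#' One excitatory and one inhibitory neuron connected recurrently with the
#' balanced weight matrix `rbind(c(w, -w), c(w, -w))`.  Its symmetric part is
#' `diag(w, -w)`: the off-diagonal (cross) terms cancel exactly, so the
#' circuit is contracting iff `w` is below the isolated-neuron leak rate.
#'
#' @param w Cross-population weight amplitude.
#' @param beta Leak rate.
#' @return List with `model`, `state` (x0 = 0), and `partition`
#'   ([ei_partition()]; neuron 1 excitatory, neuron 2 inhibitory).
#' @export
two_neuron_ei <- function(w, beta = 1) {
  wmat <- matrix(c(w, -w, w, -w), 2, 2, byrow = TRUE)
  list(model = neural_model(2, activation = "identity", beta = beta),
       state = network_state(c(0, 0), wmat),
       partition = ei_partition(1, 2, 2))
}

#' Excitatory/inhibitory population network
#'
#' Block weight matrix over an excitatory and an inhibitory population.
#' Within-block weights follow Dale's principle by column (excitatory
#' columns nonnegative, inhibitory columns nonpositive) with magnitudes
#' uniform on `[0, within_scale]` and zero diagonal.  Cross-population
#' blocks are scaled by `cross_scale`; with `exact = TRUE` the
#' inhibitory-to-excitatory block is exactly the negated transpose of the
#' excitatory-to-inhibitory block (exact balance), otherwise the two blocks
#' are drawn independently with matched mean amplitude (statistical
#' balance).
#'
#' @param n_e,n_i Population sizes (`>= 1`).
#' @param cross_scale Amplitude of the cross-population blocks.
#' @param within_scale Amplitude of the within-population weights.
#' @param exact Exact (`TRUE`) or statistical (`FALSE`) balance.
#' @param beta Leak rate.
#' @param seed Integer seed.
#' @return List with `model`, `partition` and `state` (x0 uniform on
#'   `[-1, 1]`).
#' @export
ei_population_network <- function(n_e, n_i, cross_scale = 1,
                                  within_scale = 0.05, exact = TRUE,
                                  beta = 1, seed = 0) {
  stopifnot(n_e >= 1, n_i >= 1)
  n <- n_e + n_i
  rng <- .local_rng(seed)
  e <- seq_len(n_e)
  i <- n_e + seq_len(n_i)
  w <- matrix(0, n, n)
  # within-population: E columns nonnegative, I columns nonpositive
  w[e, e] <- within_scale * matrix(rng$runif(n_e^2), n_e, n_e)
  w[i, i] <- -within_scale * matrix(rng$runif(n_i^2), n_i, n_i)
  # cross-population: E -> I nonnegative, I -> E nonpositive
  m_ie <- matrix(rng$runif(n_i * n_e), n_i, n_e)
  m_ei <- if (exact) t(m_ie) else matrix(rng$runif(n_e * n_i), n_e, n_i)
  w[i, e] <- cross_scale * m_ie
  w[e, i] <- -cross_scale * m_ei
  diag(w) <- 0
  x0 <- rng$runif(n, -1, 1)
  list(model = neural_model(n, activation = "identity", beta = beta),
       partition = ei_partition(e, i, n),
       state = network_state(x0, w))
}

#' The time-varying counterexample system
#'
#' Handle for the linear time-varying system \eqn{\dot z = A(t) z} with
#' \eqn{A(t) = \begin{pmatrix} -1 & e^{2t} \\ 0 & -1 \end{pmatrix}}: constant
#' eigenvalues \eqn{(-1, -1)} at every time, yet unstable along `x`.  The
#' closed-form solution components are included for verification.
#'
#' @return List with `A` (function of t), `rhs` (function `(t, z)`),
#'   `solution_x(t, x0, y0)` and `solution_y(t, y0)`.
#' @export
counterexample_system <- function() {
  a_fn <- function(t) matrix(c(-1, exp(2 * t), 0, -1), 2, 2, byrow = TRUE)
  list(
    A = a_fn,
    rhs = function(t, z) as.vector(a_fn(t) %*% z),
    # ydot = -y; xdot = -x + y0 e^t  =>  x = (x0 - y0/2) e^-t + y0 e^t / 2
    solution_y = function(t, y0 = 1) y0 * exp(-t),
    solution_x = function(t, x0 = 0, y0 = 1) {
      (x0 - y0 / 2) * exp(-t) + y0 / 2 * exp(t)
    }
  )
}
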