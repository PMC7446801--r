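# Fixed-step integration of the combined neural + synaptic system, with the
# sinusoid input bank, pulse perturbations, and additive neural noise.

#' Seeded bank of per-neuron sinusoid inputs
#'
#' Draws one sinusoid per neuron, \eqn{u_i(t) = a_i \sin(2\pi f_i t +
#' \phi_i)}, with frequencies uniform on `[dt, 100 dt]`, phases uniform on
#' `[0, 2*pi)` and amplitudes uniform on `[0, 20]`.  The frequency range is
#' deliberately tied to the integration step `dt` to reproduce the standard
#' figure protocol; set `physical_units = TRUE` to draw frequencies on an
#' absolute range instead.
#'
#' @param n Number of neurons.
#' @param dt Integration step the frequency range is tied to.
#' @param seed Integer seed; equal seeds give pointwise-identical banks.
#' @param amp_range Amplitude range (default `c(0, 20)`).
#' @param physical_units If `TRUE`, draw frequencies on `freq_range` directly.
#' @param freq_range Frequency range used when `physical_units = TRUE`
#'   (default `c(0.01, 1)`).
#' @return Object of class `input_bank`: components `frequencies`, `phases`,
#'   `amplitudes` and `u`, a function of time returning the length-`n` input.
#' @export
sinusoid_inputs <- function(n, dt = 1e-2, seed = 1, amp_range = c(0, 20),
                            physical_units = FALSE,
                            freq_range = c(0.01, 1)) {
  stopifnot(n >= 1)
  rng <- .local_rng(seed)
  fr <- if (physical_units) freq_range else c(dt, 100 * dt)
  f <- rng$runif(n, fr[1], fr[2])
  phi <- rng$runif(n, 0, 2 * pi)
  a <- rng$runif(n, amp_range[1], amp_range[2])
  structure(list(
    frequencies = f, phases = phi, amplitudes = a,
    u = function(t) a * sin(2 * pi * f * t + phi)
  ), class = "input_bank")
}

#' @export
print.input_bank <- function(x, ...) {
  cat(sprintf("<input_bank> n = %d, amplitudes in [%.3g, %.3g]\n",
              length(x$amplitudes), min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

# Seeded uniform draws that do not disturb the caller's RNG state.
.local_rng <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  env <- new.env()
  env$snapshot <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    assign(".Random.seed", env$snapshot, envir = globalenv())
  }
  use <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      assign(".Random.seed", env$snapshot, envir = globalenv())
      out <- f(...)
      env$snapshot <- get(".Random.seed", envir = globalenv())
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      out
    }
  }
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  list(runif = use(stats::runif), rnorm = use(stats::rnorm),
       sample_int = use(sample.int))
}

#' Simulation protocol
#'
#' Collects the numerical and stimulus settings of one run: horizon, step
#' size, seed, initial-condition rule, input bank, optional pulse
#' perturbation and noise level.  Defaults follow the standard figure
#' protocol: `dt = 1e-2`, initial conditions uniform on `[-1, 1]`, pulse of
#' value 10 lasting 100 steps starting at the midpoint, noise standard
#' deviation `sigma = 0.2` when enabled.
#'
#' @param t_end Simulation horizon (time units).
#' @param dt Fixed integration step, `> 0`.
#' @param seed Integer seed controlling initial conditions and noise.
#' @param init_range Range of the uniform initial-condition draw.
#' @param input `NULL`, an [sinusoid_inputs()] bank, or a function of time
#'   returning the length-`n` input vector.
#' @param perturbation `NULL` or a list with elements `value` (default 10),
#'   `duration_steps` (default 100) and `onset` (default `t_end/2`): a
#'   constant vector added to the input during `[onset, onset +
#'   duration_steps * dt)`.
#' @param noise_sigma Standard deviation of the independent Wiener process
#'   driving each neural unit; `0` gives a deterministic run.
#' @param record_every Record every this-many steps (thins stored output).
#' @param method `"rk4"` (deterministic default), `"euler"`, or
#'   `"euler_maruyama"` (forced whenever `noise_sigma > 0`).
#' @return Object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(t_end = 20, dt = 1e-2, seed = 1,
                                init_range = c(-1, 1), input = NULL,
                                perturbation = NULL, noise_sigma = 0,
                                record_every = 1,
                                method = c("rk4", "euler", "euler_maruyama")) {
  method <- match.arg(method)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (t_end < dt) stop("'t_end' must be >= dt", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (noise_sigma > 0) method <- "euler_maruyama"
  if (!is.null(perturbation)) {
    perturbation <- utils::modifyList(
      list(value = 10, duration_steps = 100L, onset = t_end / 2),
      perturbation)
    if (perturbation$duration_steps < 0) {
      stop("'duration_steps' must be >= 0", call. = FALSE)
    }
  }
  structure(list(t_end = t_end, dt = dt, seed = as.integer(seed),
                 init_range = init_range, input = input,
                 perturbation = perturbation, noise_sigma = noise_sigma,
                 record_every = as.integer(record_every), method = method),
            class = "simulation_protocol")
}

#' @export
print.simulation_protocol <- function(x, ...) {
  cat(sprintf(
    "<simulation_protocol> t_end = %g, dt = %g, method = %s, sigma = %g\n",
    x$t_end, x$dt, x$method, x$noise_sigma))
  invisible(x)
}

#' Fixed-step Runge-Kutta (RK4) integration
#'
#' Low-level deterministic integrator used throughout the package: classical
#' fourth-order Runge-Kutta with a fixed step, recording every
#' `record_every`-th step.  Exposed so that arbitrary (e.g. time-varying
#' linear) systems can be integrated with the same numerics as the network
#' simulator.
#'
#' @param f Function `f(t, y)` returning `dy/dt`.
#' @param y0 Initial state vector.
#' @param t_end Horizon; integration runs on `[0, t_end]`.
#' @param dt Fixed step.
#' @param record_every Record every this-many steps.
#' @return List with `times` (recorded grid, starting at 0) and `states`
#'   (matrix, one recorded time per row).
#' @export
rk4_integrate <- function(f, y0, t_end, dt, record_every = 1L) {
  .integrate_fixed(f, y0, t_end, dt, method = "rk4",
                   record_every = record_every)
}

.integrate_fixed <- function(f, y0, t_end, dt, method = "rk4",
                             record_every = 1L, noise_sigma = 0,
                             noise_dims = NULL, rng = NULL) {
  n_steps <- as.integer(round(t_end / dt))
  record_every <- max(1L, as.integer(record_every))
  rec_idx <- seq(0L, n_steps, by = record_every)
  if (rec_idx[length(rec_idx)] != n_steps) rec_idx <- c(rec_idx, n_steps)
  states <- matrix(NA_real_, length(rec_idx), length(y0))
  times <- rec_idx * dt
  y <- as.numeric(y0)
  states[1, ] <- y
  r <- 2L
  sq_dt <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    if (method == "rk4") {
      k1 <- f(t0, y)
      k2 <- f(t0 + dt / 2, y + dt / 2 * k1)
      k3 <- f(t0 + dt / 2, y + dt / 2 * k2)
      k4 <- f(t0 + dt, y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      # Euler / Euler-Maruyama; diffusion only on noise_dims
      y <- y + dt * f(t0, y)
      if (noise_sigma > 0) {
        xi <- rng$rnorm(length(noise_dims))
        y[noise_dims] <- y[noise_dims] + noise_sigma * sq_dt * xi
      }
    }
    if (r <= length(rec_idx) && k == rec_idx[r]) {
      if (!all(is.finite(y))) {
        stop(sprintf("simulation diverged: non-finite state at t = %.6g",
                     k * dt), call. = FALSE)
      }
      states[r, ] <- y
      r <- r + 1L
    }
  }
  if (!all(is.finite(y))) {
    stop(sprintf("simulation diverged: non-finite state at t = %.6g",
                 n_steps * dt), call. = FALSE)
  }
  list(times = times, states = states)
}

# Build the input function of time for a protocol (bank/function/NULL),
# optionally adding the pulse window.
.input_function <- function(protocol, n, perturbed = FALSE) {
  base <- protocol$input
  u_fn <- if (is.null(base)) {
    function(t) numeric(n)
  } else if (inherits(base, "input_bank")) {
    base$u
  } else if (is.function(base)) {
    base
  } else {
    stop("'input' must be NULL, an input_bank, or a function of time",
         call. = FALSE)
  }
  if (perturbed && !is.null(protocol$perturbation)) {
    p <- protocol$perturbation
    t_on <- p$onset
    t_off <- p$onset + p$duration_steps * protocol$dt
    val <- p$value
    function(t) u_fn(t) + if (t >= t_on && t < t_off) val else 0
  } else {
    u_fn
  }
}

#' Simulate a network under a protocol
#'
#' Integrates the combined neural + synaptic system (when `plasticity` is
#' given) or the neural system with frozen weights (when `plasticity` is
#' `NULL`).  Deterministic runs use fixed-step RK4; runs with
#' `noise_sigma > 0` use Euler-Maruyama with independent Wiener increments
#' on the neural coordinates only (weights are never driven by noise).
#' Any non-finite state aborts with an error reporting the blow-up time.
#'
#' @param model A [neural_model()].
#' @param plasticity A [plasticity_spec()], or `NULL` for static weights.
#' @param init A [network_state()] giving `x(0)` and `W(0)`.
#' @param protocol A [simulation_protocol()].
#' @param perturbed Apply the protocol's pulse perturbation to this run.
#' @param noise_seed Seed for the Wiener increments (defaults to the
#'   protocol seed).
#' @return Object of class `simulation_result`: `times`, `states` (recorded
#'   rows of the flattened state), `n`, `static`, `protocol`, `rng_record`,
#'   and `final_state` (a [network_state()]).
#' @export
simulate_network <- function(model, plasticity, init, protocol,
                             perturbed = FALSE, noise_seed = NULL) {
  n <- model$n
  stopifnot(inherits(init, "network_state"), init$n == n)
  static <- is.null(plasticity)
  u_fn <- .input_function(protocol, n, perturbed = perturbed)
  if (static) {
    w <- init$w
    act <- model$act
    leak <- model$leak
    f <- function(t, y) leak(y) + as.vector(w %*% act(y)) + u_fn(t)
    y0 <- init$x
  } else {
    k_mat <- plasticity$k_matrix
    gamma <- plasticity$gamma
    act <- model$act
    leak <- model$leak
    ix <- seq_len(n)
    f <- function(t, y) {
      x <- y[ix]
      wmat <- matrix(y[-ix], n, n, byrow = TRUE)
      dx <- leak(x) + as.vector(wmat %*% act(x)) + u_fn(t)
      dw <- -k_mat * tcrossprod(x) - gamma(t) * wmat
      c(dx, as.vector(t(dw)))
    }
    y0 <- flatten_state(init)
  }
  noise_seed <- if (is.null(noise_seed)) protocol$seed else
    as.integer(noise_seed)
  rng <- .local_rng(noise_seed)
  out <- .integrate_fixed(f, y0, protocol$t_end, protocol$dt,
                          method = if (protocol$method == "rk4" &&
                                       protocol$noise_sigma == 0) "rk4"
                                   else "euler",
                          record_every = protocol$record_every,
                          noise_sigma = protocol$noise_sigma,
                          noise_dims = seq_len(n), rng = rng)
  yT <- out$states[nrow(out$states), ]
  final <- if (static) network_state(yT, init$w) else unflatten_state(yT, n)
  structure(list(times = out$times, states = out$states, n = n,
                 static = static, protocol = protocol,
                 rng_record = list(seed = protocol$seed,
                                   noise_seed = noise_seed,
                                   kind = RNGkind()[1]),
                 final_state = final),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> n = %d, %s weights, %d recorded times on [0, %g]\n",
    x$n, if (x$static) "static" else "plastic", length(x$times),
    max(x$times)))
  invisible(x)
}

#' Draw a random initial state for a network
#'
#' Activations and (for plastic networks) weights uniform on `init_range`,
#' with a zero weight diagonal (self-feedback is carried by the leak).
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param init_range Uniform range (default `c(-1, 1)`).
#' @param w Optional fixed weight matrix (used for static networks).
#' @return A [network_state()].
#' @export
random_initial_state <- function(n, seed, init_range = c(-1, 1), w = NULL) {
  rng <- .local_rng(seed)
  x0 <- rng$runif(n, init_range[1], init_range[2])
  if (is.null(w)) {
    w <- matrix(rng$runif(n * n, init_range[1], init_range[2]), n, n)
    diag(w) <- 0
  }
  network_state(x0, w)
}

#' Paired simulations with shared inputs and distinct initial conditions
#'
#' Runs `n_pairs` pairs of simulations.  Within a pair the two members
#' receive identical inputs but independent random initial conditions; if the
#' protocol specifies a perturbation it is applied to exactly one member, and
#' if `noise_sigma > 0` each member receives independent noise.  For plastic
#' networks both `x(0)` and `W(0)` are randomized per member; for static
#' networks the weight matrix `w` is shared and only `x(0)` differs.  The
#' full-state Euclidean distance time series is returned per pair and
#' averaged across pairs.
#'
#' @inheritParams simulate_network
#' @param n_pairs Number of independent pairs.
#' @param w Weight matrix for static networks (`plasticity = NULL`).
#' @return Object of class `trial_pair_result`: `times`, `mean_distance`,
#'   `distances` (matrix, one column per pair), `pairs` (list of result
#'   pairs), `initial_distance`, `terminal_distance` (means across pairs).
#' @export
run_trial_pair <- function(model, plasticity, protocol, n_pairs = 1,
                           w = NULL) {
  stopifnot(n_pairs >= 1)
  n <- model$n
  static <- is.null(plasticity)
  if (static && is.null(w)) {
    stop("static networks need a weight matrix 'w'", call. = FALSE)
  }
  rng <- .local_rng(protocol$seed)
  seeds <- rng$sample_int(.Machine$integer.max, 4L * n_pairs)
  pairs <- vector("list", n_pairs)
  dist_mat <- NULL
  times <- NULL
  for (p in seq_len(n_pairs)) {
    s <- seeds[(p - 1) * 4 + 1:4]
    init_a <- random_initial_state(n, s[1], protocol$init_range,
                                   w = if (static) w else NULL)
    init_b <- random_initial_state(n, s[2], protocol$init_range,
                                   w = if (static) w else NULL)
    res_a <- simulate_network(model, plasticity, init_a, protocol,
                              perturbed = FALSE, noise_seed = s[3])
    res_b <- simulate_network(model, plasticity, init_b, protocol,
                              perturbed = TRUE, noise_seed = s[4])
    d <- trajectory_distance(res_a, res_b)
    if (is.null(dist_mat)) {
      dist_mat <- matrix(NA_real_, length(d$times), n_pairs)
      times <- d$times
    }
    dist_mat[, p] <- d$distances
    pairs[[p]] <- list(a = res_a, b = res_b)
  }
  mean_d <- rowMeans(dist_mat)
  structure(list(times = times, mean_distance = mean_d,
                 distances = dist_mat, pairs = pairs,
                 initial_distance = mean_d[1],
                 terminal_distance = mean_d[length(mean_d)],
                 protocol = protocol),
            class = "trial_pair_result")
}

#' @export
print.trial_pair_result <- function(x, ...) {
  cat(sprintf(
    "<trial_pair_result> %d pair(s); mean distance %.4g -> %.4g over [0, %g]\n",
    ncol(x$distances), x$initial_distance, x$terminal_distance, max(x$times)))
  invisible(x)
}
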