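# Shared helpers: seeded random matrices and a central finite-difference
# Jacobian oracle, independent of the analytic Jacobian they check.

random_matrix <- function(n, lo = -2, hi = 2) {
  matrix(stats::runif(n * n, lo, hi), n, n)
}

# central-difference Jacobian of the combined vector field
fd_combined_jacobian <- function(state, model, plasticity, t = 0, h = 1e-6) {
  y0 <- flatten_state(state)
  n <- state$n
  f <- function(y) {
    combined_rhs(unflatten_state(y, n), model, plasticity,
                 input_value = 0, t = t)
  }
  vapply(seq_along(y0), function(j) {
    e <- numeric(length(y0))
    e[j] <- h
    (f(y0 + e) - f(y0 - e)) / (2 * h)
  }, numeric(length(y0)))
}

# distance series object from raw vectors (for diagnostics tests)
make_distance_series <- function(times, distances) {
  structure(list(times = times, distances = distances),
            class = "distance_series")
}
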