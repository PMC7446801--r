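test_that("sinusoid bank respects its documented ranges and determinism", {
  b1 <- sinusoid_inputs(50, dt = 1e-2, seed = 5)
  b2 <- sinusoid_inputs(50, dt = 1e-2, seed = 5)
  b3 <- sinusoid_inputs(50, dt = 1e-2, seed = 6)
  expect_true(all(b1$amplitudes >= 0 & b1$amplitudes <= 20))
  expect_true(all(b1$frequencies >= 1e-2 & b1$frequencies <= 1))
  expect_true(all(b1$phases >= 0 & b1$phases <= 2 * pi))
  grid <- seq(0, 5, by = 0.1)
  u1 <- vapply(grid, b1$u, numeric(50))
  expect_identical(u1, vapply(grid, b2$u, numeric(50)))
  expect_false(identical(u1, vapply(grid, b3$u, numeric(50))))
  expect_true(all(abs(u1) <= b1$amplitudes + 1e-12))
})

test_that("RK4 hits the scalar linear decay to expected order", {
  m <- neural_model(1)
  st <- network_state(1, matrix(0, 1, 1))
  res <- simulate_network(m, NULL, st,
                          simulation_protocol(t_end = 2, dt = 1e-3))
  expect_lt(max(abs(res$states[, 1] - exp(-res$times))), 1e-6)
})

test_that("integrated counterexample trajectory follows its closed form", {
  sys <- counterexample_system()
  out <- rk4_integrate(sys$rhs, c(0, 1), t_end = 2, dt = 1e-4,
                       record_every = 100)
  expect_lt(max(abs(out$states[, 1] - sinh(out$times))), 1e-4)
  expect_lt(max(abs(out$states[, 2] - exp(-out$times))), 1e-4)
  expect_equal(out$states[nrow(out$states), 1], sinh(2), tolerance = 1e-6)
})

test_that("Euler-Maruyama with zero noise is exactly forward Euler", {
  m <- neural_model(2)
  st <- network_state(c(1, -1), matrix(c(0, 0.3, -0.2, 0), 2, 2))
  pe <- simulation_protocol(t_end = 1, dt = 1e-3, method = "euler")
  pm <- simulation_protocol(t_end = 1, dt = 1e-3,
                            method = "euler_maruyama")
  expect_identical(simulate_network(m, NULL, st, pe)$states,
                   simulate_network(m, NULL, st, pm)$states)
})

test_that("noise drives neural coordinates only, never the weights", {
  fx <- random_plastic_network(4, seed = 2)
  prot <- simulation_protocol(t_end = 0.5, dt = 1e-2, seed = 3,
                              noise_sigma = 0.5)
  res_noisy <- simulate_network(fx$model, fx$plasticity, fx$state, prot,
                                noise_seed = 11)
  res_noisy2 <- simulate_network(fx$model, fx$plasticity, fx$state, prot,
                                 noise_seed = 12)
  n <- 4
  # neural trajectories differ between noise seeds
  expect_false(identical(res_noisy$states[, 1:n], res_noisy2$states[, 1:n]))
  # the weight ODE sees noise only through x: same drift structure, so the
  # antisymmetric part still decays deterministically
  w_end <- res_noisy$final_state$w
  expect_true(all(is.finite(w_end)))
})

test_that("deterministic runs are bitwise reproducible from equal seeds", {
  fx <- random_plastic_network(10, seed = 1)
  inp <- sinusoid_inputs(10, dt = 1e-2, seed = 2)
  prot <- simulation_protocol(t_end = 3, dt = 1e-2, seed = 1, input = inp)
  r1 <- simulate_network(fx$model, fx$plasticity, fx$state, prot)
  r2 <- simulate_network(fx$model, fx$plasticity, fx$state, prot)
  expect_identical(r1$states, r2$states)
  tp1 <- run_trial_pair(fx$model, fx$plasticity, prot)
  tp2 <- run_trial_pair(fx$model, fx$plasticity, prot)
  expect_identical(tp1$mean_distance, tp2$mean_distance)
})

test_that("halving the step barely moves a certified deterministic run", {
  fx <- random_plastic_network(10, seed = 1)
  inp <- sinusoid_inputs(10, dt = 1e-2, seed = 2)
  p1 <- simulation_protocol(t_end = 5, dt = 1e-2, seed = 1, input = inp)
  p2 <- simulation_protocol(t_end = 5, dt = 5e-3, seed = 1, input = inp,
                            record_every = 2)
  y1 <- simulate_network(fx$model, fx$plasticity, fx$state, p1)$final_state
  y2 <- simulate_network(fx$model, fx$plasticity, fx$state, p2)$final_state
  rel <- sqrt(sum((flatten_state(y1) - flatten_state(y2))^2)) /
    sqrt(sum(flatten_state(y1)^2))
  expect_lt(rel, 1e-4)
})

test_that("the fixed-step integrator agrees with an established ODE solver", {
  skip_if_not_installed("deSolve")
  fx <- random_plastic_network(5, seed = 7)
  n <- 5
  f <- function(t, y, parms) {
    st <- unflatten_state(y, n)
    list(combined_rhs(st, fx$model, fx$plasticity, 0, t))
  }
  times <- seq(0, 2, by = 1e-2)
  ref <- deSolve::ode(flatten_state(fx$state), times, f, NULL,
                      method = "rk4")
  mine <- simulate_network(fx$model, fx$plasticity, fx$state,
                           simulation_protocol(t_end = 2, dt = 1e-2))
  expect_equal(mine$states[nrow(mine$states), ],
               unname(ref[nrow(ref), -1]), tolerance = 1e-10)
})

test_that("divergence aborts with a blow-up time", {
  # strong positive feedback, no plasticity to rescue it
  m <- neural_model(2)
  w <- matrix(5, 2, 2)
  st <- network_state(c(1, 1), w)
  expect_error(simulate_network(m, NULL, st,
                                simulation_protocol(t_end = 100, dt = 0.1)),
               "diverged")
})

test_that("pulse perturbation separates trials and recovery follows", {
  fx <- random_plastic_network(15, seed = 2)
  inp <- sinusoid_inputs(15, dt = 1e-2, seed = 3)
  prot <- simulation_protocol(t_end = 10, dt = 1e-2, seed = 2, input = inp,
                              perturbation = list(value = 10,
                                                  duration_steps = 100L,
                                                  onset = 4),
                              record_every = 2)
  tp <- run_trial_pair(fx$model, fx$plasticity, prot)
  d <- tp$mean_distance
  tt <- tp$times
  pre_peak <- max(d[tt < 4])
  pulse_peak <- max(d[tt >= 4 & tt < 5.2])
  pre_level <- d[max(which(tt < 4))]
  final <- d[length(d)]
  expect_gt(pulse_peak, 3 * pre_level)  # distance rises during the pulse
  expect_lt(final, pulse_peak)          # and decays after offset
  expect_lt(final, pre_peak)
})

test_that("protocol validation catches bad steps and windows", {
  expect_error(simulation_protocol(dt = 0), "dt")
  expect_error(simulation_protocol(t_end = 1e-3, dt = 1e-2), "t_end")
  expect_error(simulation_protocol(noise_sigma = -1), "noise_sigma")
  expect_error(simulation_protocol(
    perturbation = list(duration_steps = -1)), "duration_steps")
})
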