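test_that("learning-rate hypotheses accept the equal-rate case and reject violations", {
  ok <- check_plasticity_hypotheses(plasticity_spec(1, n = 3))
  expect_true(ok$passed)
  expect_true(all(ok$assumptions_checked))

  bad_psd <- check_plasticity_hypotheses(
    plasticity_spec(matrix(c(1, 2, 2, 1), 2, 2)))
  expect_false(bad_psd$passed)
  expect_false(bad_psd$assumptions_checked[["positive_semidefinite"]])

  bad_sign <- check_plasticity_hypotheses(
    plasticity_spec(matrix(c(1, -0.5, -0.5, 1), 2, 2)))
  expect_false(bad_sign$passed)
  expect_false(bad_sign$assumptions_checked[["entrywise_positive"]])

  bad_sym <- check_plasticity_hypotheses(
    plasticity_spec(matrix(c(1, 2, 1, 1), 2, 2)))
  expect_false(bad_sym$assumptions_checked[["symmetric"]])
})

test_that("a certificate report passes only with all checks and positive margins", {
  r <- certificate_report("demo", margins = c(a = 1),
                          assumptions_checked = c(ok = TRUE))
  expect_true(r$passed)
  expect_false(certificate_report("demo", margins = c(a = -1),
                                  assumptions_checked = c(ok = TRUE))$passed)
  expect_false(certificate_report("demo", margins = c(a = 1),
                                  assumptions_checked = c(ok = FALSE))$passed)
  expect_false(certificate_report("demo", margins = c(a = 0),
                                  assumptions_checked = c(ok = TRUE))$passed)
})

test_that("plasticity certificate passes a small equal-rate network", {
  cert <- hebbian_contraction_certificate(neural_model(2),
                                          plasticity_spec(1, n = 2),
                                          seed = 1)
  expect_true(cert$passed)
  expect_true(all(cert$margins > 0))
  expect_match(cert$details$metric, "K-rescaled")
})

test_that("plasticity certificate fails on bad K or zero forgetting", {
  bad_k <- hebbian_contraction_certificate(
    neural_model(2), plasticity_spec(matrix(c(1, 2, 2, 1), 2, 2)))
  expect_false(bad_k$passed)
  expect_true("positive_semidefinite" %in% bad_k$details$failed_checks)

  no_gamma <- hebbian_contraction_certificate(
    neural_model(2), plasticity_spec(1, n = 2, gamma = 0))
  expect_false(no_gamma$passed)
  expect_true("gamma_positive" %in% no_gamma$details$failed_checks)

  nonlinear <- hebbian_contraction_certificate(
    neural_model(2, activation = "tanh"), plasticity_spec(1, n = 2))
  expect_false(nonlinear$passed)
})

test_that("dense and matrix-free metric-transformed mu2 agree", {
  fx <- random_plastic_network(8, seed = 3)
  jac <- combined_jacobian(fx$state, fx$model, fx$plasticity, 0)
  sc <- contractnet:::plasticity_metric_scales(fx$plasticity)
  dense <- mu2(jac * tcrossprod(sc, 1 / sc))
  mv <- contractnet:::.make_sym_jacobian_matvec(fx$state, fx$model,
                                                fx$plasticity, 0)
  expect_equal(contractnet:::.lanczos_lambda_max(mv, 8 + 64), dense,
               tolerance = 1e-9)
})

test_that("sparsity margins reproduce hand-computed values", {
  m <- neural_model(1, activation = "tanh")
  r1 <- sparsity_certificate(m, sparsity_profile(1, 0.5, w_max = 0.1))
  expect_equal(unname(r1$margins), 0.4)
  expect_true(r1$passed)
  r2 <- sparsity_certificate(m, sparsity_profile(2, 0.5, w_max = 0.1))
  expect_equal(unname(r2$margins), -0.2)
  expect_false(r2$passed)
  # disconnected network is trivially contracting with margin beta
  r0 <- sparsity_certificate(neural_model(3, beta = 2),
                             sparsity_profile(0, 0, w_max = 1, n = 3))
  expect_equal(unname(r0$margins), rep(2, 3))
  expect_true(r0$passed)
})

test_that("sparsity certificate demands a bounded activation for plastic synapses", {
  m_lin <- neural_model(1, activation = "identity")
  expect_error(sparsity_certificate(m_lin,
                                    sparsity_profile(1, 0.5, w_max = 0.1)),
               "bounded activation")
  # alpha = 0 is fine with an unbounded activation
  expect_true(sparsity_certificate(
    m_lin, sparsity_profile(1, 0, w_max = 0.1))$passed)
})

test_that("sparsity margins are monotone in p, w_max, alpha and beta", {
  m <- neural_model(1, activation = "tanh")
  margin <- function(p, w_max = 0.1, alpha = 0.5, beta = 1) {
    mm <- neural_model(1, activation = "tanh", beta = beta)
    unname(sparsity_certificate(mm,
                                sparsity_profile(p, alpha,
                                                 w_max = w_max))$margins)
  }
  ps <- 0:6
  ms <- vapply(ps, margin, numeric(1))
  expect_equal(diff(ms), rep(-(1 * 0.1 + 0.5 * 1), 6))  # affine in p
  expect_true(all(diff(vapply(c(0.1, 0.2, 0.4),
                              function(w) margin(2, w_max = w),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0, 0.3, 0.9),
                              function(a) margin(2, alpha = a),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(1, 2, 4),
                              function(b) margin(2, beta = b),
                              numeric(1))) > 0))
})

test_that("static symmetric-part certificate follows the worked two-neuron case", {
  m <- neural_model(2)
  # antisymmetric weights contribute nothing
  w_anti <- matrix(c(0, -3, 3, 0), 2, 2)
  r <- static_symmetric_part_certificate(w_anti, m)
  expect_true(r$passed)
  expect_equal(unname(r$margins), 1)

  r05 <- static_symmetric_part_certificate(two_neuron_ei(0.5)$state$w, m)
  expect_true(r05$passed)
  expect_equal(unname(r05$margins), 0.5)

  r2 <- static_symmetric_part_certificate(two_neuron_ei(2)$state$w, m)
  expect_false(r2$passed)
  expect_equal(unname(r2$margins), -1)
})

test_that("exact E-I balance is invariant to cross-block amplitude", {
  margins <- vapply(c(1, 10, 100), function(s) {
    fx <- ei_population_network(15, 15, cross_scale = s,
                                within_scale = 0.02, exact = TRUE, seed = 4)
    r <- ei_balance_certificate(fx$state$w, fx$partition, fx$model)
    expect_true(r$passed)
    unname(r$margins)
  }, numeric(1))
  expect_equal(max(margins) - min(margins), 0, tolerance = 1e-12)
})

test_that("positive cross-block feedback at large amplitude fails the balance test", {
  fx <- ei_population_network(10, 10, cross_scale = 5, exact = TRUE,
                              seed = 1)
  w <- fx$state$w
  e <- fx$partition$excitatory
  i <- fx$partition$inhibitory
  w[e, i] <- -w[e, i]  # flip I->E sign: now W_EI = +W_IE^T
  r <- ei_balance_certificate(w, fx$partition, fx$model)
  expect_false(r$passed)
  expect_false(r$assumptions_checked[["dale_signs"]])
  expect_true(unname(r$margins) < 0)  # sym part acquires large cross blocks
})

test_that("the two-neuron circuit is the E-I certificate's base case", {
  fx <- two_neuron_ei(0.5)
  r_ei <- ei_balance_certificate(fx$state$w, fx$partition, fx$model,
                                 tolerance = 0)
  r_static <- static_symmetric_part_certificate(fx$state$w, fx$model)
  expect_equal(unname(r_ei$margins), unname(r_static$margins))
  expect_equal(r_ei$passed, r_static$passed)
})

test_that("partition validation rejects overlaps and gaps", {
  expect_error(ei_partition(1:3, 3:4, 4), "overlap|cover")
  expect_error(ei_partition(1, 3, 3), "cover")
  expect_error(ei_balance_certificate(diag(3), ei_partition(1, 2, 2),
                                      neural_model(3)), "partition")
})

test_that("echo-state discrete check uses the largest singular value", {
  r <- esn_discrete_contraction_check(0.5 * diag(3))
  expect_true(r$passed)
  expect_equal(unname(r$margins), 0.5)
  expect_false(esn_discrete_contraction_check(diag(c(2, 0.1)))$passed)
  # scaled rotation: sigma_max equals the scale
  th <- pi / 7
  rot <- 0.9 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(unname(esn_discrete_contraction_check(rot)$margins), 0.1,
               tolerance = 1e-12)
})

test_that("constant eigenvalues coexist with an unstable trajectory", {
  demo <- eigenvalue_test_insufficiency_demo()
  # eigenvalues of the triangular A(t) are (-1, -1) at every sampled time
  expect_true(all(abs(demo$eigenvalues + 1) < 1e-12))
  # trajectory matches sinh/exp closed form; x grows monotonically
  expect_lt(demo$max_abs_error, 1e-4)
  x <- demo$integrated[, "x"]
  expect_true(all(diff(x) > 0))
  expect_equal(x[which.min(abs(demo$times - 1))], sinh(1), tolerance = 1e-6)
  # mu2 starts at -0.5 and crosses zero at ln(2)/2
  expect_equal(demo$mu2_values[1], -0.5)
  expect_equal(demo$mu2_zero_crossing, log(2) / 2, tolerance = 1e-6)
})
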