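test_that("period estimator recovers known signals and rejects flat ones", {
  dt <- 0.01
  tt <- seq(0, 20, by = dt)
  expect_equal(estimate_period(sin(2 * pi * tt / 2), dt), 2,
               tolerance = 0.005)
  expect_true(is.na(estimate_period(rep(3.2, length(tt)), dt)))
  # mixture with a fast ripple and noise still yields the fundamental
  set.seed(1)
  x <- sin(2 * pi * tt / 2) + 0.3 * sin(2 * pi * tt / 0.37) +
    rnorm(length(tt), sd = 0.1)
  expect_equal(estimate_period(x, dt), 2, tolerance = 0.02)
  # pure noise is aperiodic
  set.seed(2)
  expect_true(is.na(estimate_period(rnorm(2001), dt)))
  expect_error(estimate_period(1:4, dt), "short")
})

test_that("phase difference: zero, anti-phase, quarter shift", {
  dt <- 0.01
  tt <- seq(0, 20, by = dt)
  a <- sin(2 * pi * tt / 2)
  expect_equal(phase_difference(a, a, 2, dt), 0)
  expect_equal(abs(phase_difference(a, -a, 2, dt)), pi, tolerance = 0.05)
  b <- sin(2 * pi * (tt - 0.5) / 2)  # lags a by a quarter period
  expect_equal(phase_difference(a, b, 2, dt), pi / 2, tolerance = 0.05)
  expect_error(phase_difference(a, a, NA, dt), "periodic")
})

test_that("responsiveness cut-off and active fraction", {
  vth <- c(-30, -30, -30)
  V <- rbind(c(-30, -30, -30), c(-28, -10, -29))
  act <- c(TRUE, TRUE, TRUE)
  r <- responsive_neurons(V, vth, act, c("A", "B", "C"), threshold_mV = 5)
  expect_equal(r$responsive, "B")
  expect_equal(r$active_fraction, 1 / 3)
  # resting network: empty set, fraction 0
  r0 <- responsive_neurons(V[1, , drop = FALSE], vth, act,
                           c("A", "B", "C"))
  expect_length(r0$responsive, 0)
  expect_equal(r0$active_fraction, 0)
  # fraction invariant under relabeling
  perm <- c(3, 1, 2)
  rp <- responsive_neurons(V[, perm], vth[perm], act[perm],
                           c("C", "A", "B"))
  expect_equal(rp$active_fraction, r$active_fraction)
})

test_that("the ring oscillator scenario reproduces its reference period", {
  r <- fixture("ring_oscillator")
  spec <- scenario_spec("ring", stimuli_nA = list(R1 = 0.02, R2 = 0.02,
                                                  R3 = 0.02),
                        duration = 20, settle_time = 5, seed = 7)
  res <- run_scenario(spec, r$connectome, r$params)
  expect_setequal(res$responsive, c("R1", "R2", "R3"))
  expect_equal(res$consensus_period, r$expected$period,
               tolerance = r$expected$period_rel_tol)
  # the three ring neurons oscillate mutually out of phase
  ph <- res$phases[c("R1", "R2", "R3")]
  expect_true(all(is.finite(ph)))
  others <- abs(ph[ph != 0])
  expect_true(all(others > pi / 3))
  # determinism given the seed
  res2 <- run_scenario(spec, r$connectome, r$params)
  expect_identical(res2$V, res$V)
})

test_that("a zero-stimulus network is classified as silent", {
  c1 <- prop_net(3, n = 6)
  spec <- scenario_spec("rest", duration = 4, settle_time = 1, seed = 3)
  res <- run_scenario(spec, c1)
  expect_length(res$responsive, 0)
  expect_true(all(is.na(res$periods)))
  expect_true(is.na(res$consensus_period))
})

test_that("scenario ablation removes the neurons before integration", {
  r <- fixture("ring_oscillator")
  spec <- scenario_spec("cut", stimuli_nA = list(R1 = 0.02, R2 = 0.02,
                                                 R3 = 0.02),
                        ablated = "R2", duration = 8, settle_time = 4,
                        seed = 7)
  res <- run_scenario(spec, r$connectome, r$params)
  # the broken ring cannot sustain the frustrated oscillation
  expect_false(isTRUE(res$consensus_period > 0.5 &&
                        res$consensus_period < 1.5 &&
                        length(res$responsive) == 3))
})

test_that("robustness scan: zero perturbation reproduces the baseline", {
  r <- fixture("ring_oscillator")
  spec <- scenario_spec("ring", stimuli_nA = list(R1 = 0.02, R2 = 0.02,
                                                  R3 = 0.02),
                        duration = 10, settle_time = 4, seed = 7)
  base <- run_scenario(spec, r$connectome, r$params)
  scan0 <- robustness_scan(spec, r$connectome, r$params,
                           perturbation = 0, n_draws = 2, seed = 1)
  expect_equal(scan0$period, rep(base$consensus_period, 2))
  # draws are reproducible given the seed
  scan1 <- robustness_scan(spec, r$connectome, r$params,
                           perturbation = 0.2, n_draws = 2, seed = 5)
  scan2 <- robustness_scan(spec, r$connectome, r$params,
                           perturbation = 0.2, n_draws = 2, seed = 5)
  expect_identical(scan1, scan2)
  # the ring's oscillation is robust to +/-20% perturbations
  expect_true(all(scan1$oscillating))
})

test_that("built-in scenario specs carry the published amplitudes", {
  f <- builtin_scenario("forward")
  expect_equal(f$stimuli_nA, list(PLM = 1.4, AVB = 2.3))
  b <- builtin_scenario("backward")
  expect_equal(b$stimuli_nA, list(ALM = 5.8, AVA = 2.0, AVD = 1.0,
                                  AVE = 1.0))
  a <- builtin_scenario("forward_avb_ablated")
  expect_equal(a$ablated, "AVB")
  expect_equal(a$stimuli_nA$PLM, 1.4)
  # class expansion against a roster
  nm <- c("PLML", "PLMR", "AVBL", "AVBR", "AVAL")
  expect_setequal(expand_neuron_class(nm, "PLM"), c("PLML", "PLMR"))
  expect_equal(expand_neuron_class(nm, "AVAL"), "AVAL")
  expect_error(expand_neuron_class(nm, "XYZ"), "match")
  pr <- builtin_preset("forward", nm)
  expect_equal(pr$stimuli_nA$PLML, 1.4)
  expect_equal(pr$stimuli_nA$AVBR, 2.3)
})
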