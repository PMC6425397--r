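cfg <- solver_config()

test_that("initial condition draw is deterministic and correctly scaled", {
  a <- init_state(279, seed = 5)
  b <- init_state(279, seed = 5)
  expect_identical(a, b)
  expect_equal(length(a$V) + length(a$s), 558)
  expect_true(all(a$s >= 0 & a$s <= 1))
  expect_true(all(abs(a$V) < 1e-2))  # 1e-4-scale draw
  # half-normal mean of |V| over many draws: sigma * sqrt(2/pi) * 1e-4
  vs <- unlist(lapply(1:200, function(k) init_state(20, seed = k)$V))
  expect_equal(mean(abs(vs)), 0.94e-4 * sqrt(2 / pi), tolerance = 0.05)
  # caller's RNG stream is untouched
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(init_state(10, seed = 99)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("leak-only decay matches the exponential closed form to 1e-6 mV", {
  f <- fixture("single")
  sched <- stimulus_schedule(1)
  st <- network_state(0, -25, 0)
  blk <- integrate_block(st, f$connectome, f$params, sched, cfg,
                         block_dt = 0.5)
  exact <- -35 + (-25 - (-35)) * exp(-blk$times / 0.15)
  expect_lt(max(abs(blk$V[, 1] - exact)), 1e-6)
})

test_that("a network started at its fixed point stays there", {
  s <- fixture("syn_pair")
  p <- s$params
  # fixed point: V = vth (by construction Phi = 1/2 there), s = s_eq
  vth <- compute_vth(s$connectome, p, 0)
  st <- network_state(0, vth, rep(s_equilibrium(p$a_r, p$a_d), 2))
  blk <- integrate_block(st, s$connectome, p, stimulus_schedule(2), cfg,
                         vth = vth, block_dt = 0.5)
  expect_lt(max(abs(blk$end_state$V - vth)), 1e-6)
})

test_that("block integration is reproducible bit-identically", {
  c1 <- prop_net(1)
  p <- model_params(c1)
  sched <- stimulus_schedule(c1$n, baseline_nA = 0.001)
  st <- init_state(c1$n, seed = 2)
  b1 <- integrate_block(st, c1, p, sched, cfg)
  b2 <- integrate_block(st, c1, p, sched, cfg)
  expect_identical(b1$V, b2$V)
  expect_identical(b1$s, b2$s)
})

test_that("one long block equals chained short blocks within 10 atol", {
  c1 <- prop_net(4)
  p <- model_params(c1)
  sched <- stimulus_schedule(c1$n, baseline_nA = 0.0005)
  st <- init_state(c1$n, seed = 3)
  vth <- compute_vth(c1, p, evaluate_stimulus(sched, 0))
  one <- integrate_block(st, c1, p, sched, cfg, vth = vth, block_dt = 0.1)
  a <- integrate_block(st, c1, p, sched, cfg, vth = vth, block_dt = 0.05)
  b <- integrate_block(a$end_state, c1, p, sched, cfg, vth = vth,
                       block_dt = 0.05)
  expect_lt(max(abs(one$end_state$V - b$end_state$V)), 1e-5)
})

test_that("halving tolerances changes trajectories less than the coarser", {
  c1 <- prop_net(6)
  p <- model_params(c1)
  sched <- stimulus_schedule(c1$n, baseline_nA = 0.001)
  st <- init_state(c1$n, seed = 4)
  vth <- compute_vth(c1, p, evaluate_stimulus(sched, 0))
  coarse <- integrate_block(st, c1, p, sched,
                            solver_config(rtol = 1e-6, atol = 1e-8),
                            vth = vth, block_dt = 0.5)
  fine <- integrate_block(st, c1, p, sched,
                          solver_config(rtol = 5e-7, atol = 5e-9),
                          vth = vth, block_dt = 0.5)
  # global error may exceed the per-step tolerance by a small accumulation
  # factor over the half-second horizon
  expect_lt(max(abs(coarse$V - fine$V)) / max(abs(fine$V)), 3e-6)
})

test_that("synaptic activity stays in [0, 1] on random driven networks", {
  for (seed in 1:20) {
    c1 <- prop_net(seed)
    p <- model_params(c1)
    sched <- stimulus_schedule(c1$n)
    sched <- set_stimulus(sched, 1 + seed %% c1$n, 0.05, t_now = 0)
    tl <- integrate_session(0.5, c1, p, sched,
                            solver_config(seed = seed))
    sm <- timeline_samples(tl)
    expect_true(all(sm$s >= -1e-9 & sm$s <= 1 + 1e-9))
    expect_true(all(is.finite(sm$V)))
  }
})

test_that("voltages stay bounded by the drive on random networks", {
  for (seed in 1:5) {
    c1 <- prop_net(seed)
    p <- model_params(c1)
    I_nA <- 0.01
    sched <- stimulus_schedule(c1$n, baseline_nA = I_nA)
    tl <- integrate_session(1, c1, p, sched, solver_config(seed = seed))
    sm <- timeline_samples(tl)
    # each membrane is a conductance-weighted average of reversal
    # potentials plus I/G_leak at most
    upper <- 0 + nA_to_arb(I_nA) / 0.1
    expect_true(all(sm$V >= min(-48, -35) - 1e-6))
    expect_true(all(sm$V <= upper + 1e-6))
  }
})

test_that("structural events leave disconnected components untouched", {
  # two gap pairs with no cross connections; ablating one pair's neuron
  # must not change the other pair's trajectory
  gap <- matrix(0, 4, 4)
  gap[1, 2] <- gap[2, 1] <- 1
  gap[3, 4] <- gap[4, 3] <- 1
  c1 <- make_conn(gap, matrix(0, 4, 4))
  p <- model_params(c1)
  sched <- stimulus_schedule(4, baseline_nA = c(0.0002, 0, 0.0002, 0))
  st <- init_state(4, seed = 8)
  base <- integrate_session(0.4, c1, p, sched, cfg, state = st)
  abl <- integrate_session(0.4, c1, p, sched, cfg, state = st,
                           events = list(list(t = 0.2, type = "ablate",
                                              neurons = 1)))
  sb <- timeline_samples(base)
  sa <- timeline_samples(abl)
  expect_equal(sa$V[, 3:4], sb$V[, 3:4], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sa$V[, 2], sb$V[, 2])))
})

test_that("ablate-then-reinsert at the same boundary equals never ablating", {
  c1 <- prop_net(2)
  p <- model_params(c1)
  sched <- stimulus_schedule(c1$n, baseline_nA = 0.001)
  st <- init_state(c1$n, seed = 1)
  base <- integrate_session(0.3, c1, p, sched, cfg, state = st)
  noop <- integrate_session(0.3, c1, p, sched, cfg, state = st,
                            events = list(
                              list(t = 0.1, type = "ablate", neurons = 2),
                              list(t = 0.1, type = "reinsert", neurons = 2)))
  expect_identical(timeline_samples(noop)$V, timeline_samples(base)$V)
})

test_that("ablating every neuron relaxes all voltages to the leak potential", {
  c1 <- prop_net(5, n = 4)
  p <- model_params(c1)
  st <- network_state(0, c(-10, -20, -50, -60), rep(0.3, 4))
  tl <- integrate_session(2.5, ablate(c1, 1:4), p, stimulus_schedule(4),
                          cfg, state = st)
  # after ~17 membrane time constants every cell sits at E_cell
  expect_lt(max(abs(tl$blocks[[length(tl$blocks)]]$end_state$V - (-35))),
            1e-3)
})

test_that("gap-only networks settle onto the threshold-solver fixed point", {
  # with no synapses the fixed point of the dynamics is exactly the linear
  # system the threshold solver solves (laplacian mode) -- oracle equivalence
  for (seed in c(3, 11)) {
    c1 <- random_connectome(synth_spec(n = 6, gap_density = 0.5,
                                       syn_density = 0, seed = seed))
    p <- model_params(c1)
    I <- rep(0, 6); I[1] <- 2
    sched <- stimulus_schedule(6, baseline_nA = arb_to_nA(I))
    vth <- compute_vth(c1, p, I)
    tl <- integrate_session(3, c1, p, sched, cfg,
                            state = init_state(6, seed = seed))
    final <- tl$blocks[[length(tl$blocks)]]$end_state$V
    expect_equal(final, vth, tolerance = 1e-6)
  }
})
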