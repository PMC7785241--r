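test_that("protocol validation rejects malformed inputs", {
  expect_error(protocol(-5), "duration")
  expect_error(protocol(100, segments = data.frame(start = 50, stop = 200,
                                                   amplitude = 1)),
               "within")
  expect_error(protocol(100, segments = data.frame(start = 10, stop = 5,
                                                   amplitude = 1)),
               "start < stop")
  expect_error(protocol(100, alpha_schedule = data.frame(time = c(0, 50),
                                                         alpha = c(1, 2))),
               "alpha")
  pr <- step_protocol(30, onset = 200, offset = 700, duration = 1000)
  expect_equal(protocol_current(pr, c(100, 300, 800)), c(0, 30, 0))
})

test_that("bistable preset: hyperpolarizing step switches up- to
           down-state", {
  p <- load_preset("fig3_bistable")$model
  fp <- find_fixed_points(p)
  up <- fp[which.max(fp$V), ]
  dn <- fp[which.min(fp$V), ]
  r <- simulate_neuron(p, step_protocol(-60, onset = 200, offset = 1200,
                                        duration = 8000),
                       state0 = neuron_state(up$V, up$eps))
  n <- length(r$V)
  expect_lt(abs(r$V[n] - dn$V), 0.1)
  expect_lt(abs(r$eps[n] - dn$eps), 0.01)
})

test_that("bistable preset: strong step gives spiking then block, then
           returns toward the up-state", {
  p <- load_preset("fig3_bistable")$model
  fp <- find_fixed_points(p)
  up <- fp[which.max(fp$V), ]
  saddle <- fp[fp$stability != "stable", ]
  r <- simulate_neuron(p, step_protocol(80, onset = 200, offset = 1200,
                                        duration = 4000),
                       state0 = neuron_state(up$V, up$eps))
  expect_gt(sum(r$spikes <= 1200), 5)
  b <- detect_depolarization_block(r)
  expect_gt(nrow(b), 0)
  # the block covers the stimulated tail, through the offset
  expect_lt(b$start[1], 1200)
  expect_gt(b$stop[1], 1200)
  # after offset the neuron stays in the up-state basin (never crosses the
  # saddle towards the hyperpolarized down-state)
  post <- r$times > 1300
  expect_true(all(r$eps[post] < saddle$eps))
  expect_true(all(r$V[post] > -70))
})

test_that("energy accounting: delta at each reset, smooth flow between", {
  p <- load_preset("fig3_bistable")$model
  dt <- 0.05
  r <- simulate_neuron(p, step_protocol(75, onset = 100, offset = 1100,
                                        duration = 1200), dt = dt)
  expect_gt(length(r$spikes), 3)
  idx <- match(round(r$spikes / dt), round(r$times / dt))
  # eps drops by exactly delta at the reset, on top of one smooth RK4 step
  for (i in idx) {
    ref <- rk4_elif_segment(p, r$V[i - 1], r$eps[i - 1],
                            r$times[(i - 1):i],
                            I = protocol_current(r$protocol, r$times[i - 1]))
    expect_equal(ref$eps[2] - r$eps[i], p$delta, tolerance = 1e-9)
  }
  # between two spikes the recorded trace obeys the smooth flow (RK4 oracle)
  seg <- which(r$times > r$spikes[1] & r$times < r$spikes[2])
  seg <- seg[-length(seg)]
  ref <- rk4_elif_segment(p, r$V[seg[1]], r$eps[seg[1]], r$times[seg],
                          I = 75)
  expect_lt(max(abs(ref$V - r$V[seg])), 1e-9)
  expect_lt(max(abs(ref$eps - r$eps[seg])), 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- load_preset("fig5_network_neuron")$model
  pr <- protocol(2000, poisson = list(rate = 500, weight = 100))
  r1 <- simulate_neuron(p, pr, seed = 11)
  r2 <- simulate_neuron(p, pr, seed = 11)
  r3 <- simulate_neuron(p, pr, seed = 12)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$V, r2$V)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("eLIF never spikes while eps < epsc", {
  p <- load_preset("fig3_bistable")$model
  r <- simulate_neuron(p, step_protocol(80, onset = 100, offset = 2100,
                                        duration = 2200))
  expect_gt(length(r$spikes), 0)
  i <- match(round(r$spikes / r$dt), round(r$times / r$dt))
  # recorded sample at spike time is post-reset: add delta back
  expect_true(all(r$eps[i] + p$delta >= p$epsc - 1e-9))
})

test_that("spike times are strictly increasing and traces finite", {
  for (nm in c("fig3_bistable", "fig6_RB", "fig6_IS")) {
    cfg <- load_preset(nm)
    r <- simulate_neuron(cfg$model, cfg$protocol)
    if (length(r$spikes) > 1) expect_true(all(diff(r$spikes) > 0))
    expect_true(all(is.finite(r$V)))
    expect_true(all(is.finite(r$eps)))
  }
})

test_that("death is declared when energy depletes at high potential, then
           the state freezes", {
  p <- elif_params(E0 = -65, Eu = -50, Ef = -60, Ed = -45, Vth = -50,
                   Vr = -55, epsc = 0.5, delta = 0.2, tau_e = 100)
  r <- simulate_neuron(p, step_protocol(400, onset = 100, offset = 2000,
                                        duration = 2500))
  expect_false(is.na(r$death_time))
  post <- r$times > r$death_time
  expect_equal(length(unique(r$V[post])), 1L)
  expect_equal(length(unique(r$eps[post])), 1L)
  expect_true(all(r$spikes <= r$death_time))
})

test_that("numerical blow-up raises an error naming the step", {
  p <- elif_params()
  pr <- protocol(60000, segments = data.frame(start = 0, stop = 60000,
                                              amplitude = -500))
  expect_error(simulate_neuron(p, pr, dt = 100, method = "euler"),
               "diverged at step")
})

test_that("depolarization-block detection matches its definition", {
  # tonic regular spiking: no block
  p0 <- elif_params(E0 = -65, Eu = -65, Vth = -50, Vr = -65, delta = 0,
                    epsc = 0)
  r0 <- simulate_neuron(p0, step_protocol(200, onset = 100, offset = 1100,
                                          duration = 1200))
  expect_gt(length(r0$spikes), 10)
  expect_equal(nrow(detect_depolarization_block(r0)), 0L)
  # driven above the upper bifurcation with eps pinned below epsc
  p <- load_preset("fig3_bistable")$model
  sn <- saddle_node_currents(p)
  r <- simulate_neuron(p, step_protocol(sn[["I_plus"]] + 15, onset = 200,
                                        offset = 1200, duration = 1400))
  b <- detect_depolarization_block(r)
  expect_gt(nrow(b), 0)
  i <- r$times >= b$start[1] & r$times <= b$stop[1]
  expect_true(all(r$eps[i] < p$epsc))
  expect_true(all(r$V[i] >= p$Vth))
})

test_that("integrator convergence under dt halving for every preset", {
  for (nm in preset_names()) {
    cfg <- load_preset(nm)
    r1 <- simulate_neuron(cfg$model, cfg$protocol, dt = 0.05)
    r2 <- simulate_neuron(cfg$model, cfg$protocol, dt = 0.025)
    expect_lte(abs(length(r1$spikes) - length(r2$spikes)), 1)
    n <- min(length(r1$spikes), length(r2$spikes))
    if (n == 0) next
    expect_lte(abs(r1$spikes[1] - r2$spikes[1]), 2 * 0.05)
    # later spikes: 2 dt plus a linear phase-drift allowance (end-of-step
    # spike times carry a <= dt bias per spike that accumulates)
    onset <- if (!is.null(cfg$protocol$segments))
      min(cfg$protocol$segments$start) else 0
    bound <- 2 * 0.05 + 0.005 * pmax(r1$spikes[seq_len(n)] - onset, 0)
    expect_true(all(abs(r1$spikes[seq_len(n)] - r2$spikes[seq_len(n)]) <=
                    bound))
  }
})

test_that("alpha schedules and refractoriness are honored", {
  p <- load_preset("fig4_disease")$model
  pr <- protocol(3000, alpha_schedule = data.frame(time = c(0, 3000),
                                                   alpha = c(1, 0.35)))
  r <- simulate_neuron(p, pr)
  # declining health ends depolarized relative to the healthy rest
  expect_gt(r$V[length(r$V)], effective_leak(p$eps0, p) + 2)
  p2 <- elif_params(E0 = -65, Eu = -65, Vth = -50, Vr = -65, delta = 0,
                    epsc = 0)
  pr2 <- step_protocol(500, onset = 0, offset = 1000, duration = 1000)
  r_fast <- simulate_neuron(p2, pr2, refractory = 0)
  r_slow <- simulate_neuron(p2, pr2, refractory = 5)
  expect_gt(length(r_fast$spikes), length(r_slow$spikes))
  expect_true(all(diff(r_slow$spikes) >= 5 - 1e-9))
})
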