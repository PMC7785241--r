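test_that("effective_leak matches its defining affine law", {
  p <- elif_params(E0 = -65, Eu = -50)
  expect_equal(effective_leak(p$eps0, p), -65)
  expect_equal(effective_leak(0, p), -50)
  expect_equal(effective_leak(2 * p$eps0, p), -80)
  # slope is -(Eu - E0)/eps0; integrator regime: lower energy, higher leak
  eps <- seq(-1, 3, by = 0.25)
  slopes <- diff(effective_leak(eps, p)) / diff(eps)
  expect_equal(slopes, rep(-(p$Eu - p$E0) / p$eps0, length(slopes)))
  expect_true(all(diff(effective_leak(eps, p)) < 0))
})

test_that("katp_current follows the stated saturation law", {
  p <- madexp_params(epsc = 0.2, I_KATP = 40)
  expect_equal(katp_current(0, p), 40)
  expect_equal(katp_current(p$epsc / 2, p), 20)
  expect_lt(katp_current(1e9, p), 1e-6)
  eps <- seq(0, 5, by = 0.1)
  expect_true(all(diff(katp_current(eps, p)) < 0))
  # epsc = 0 makes the channel inert (documented degenerate limit)
  p0 <- madexp_params(epsc = 0, I_KATP = 40)
  expect_equal(katp_current(c(0, 1, 10), p0), c(0, 0, 0))
})

test_that("elif_rhs reproduces the flow of the membrane/energy equations", {
  p <- elif_params()
  # both energy terms vanish at (V = Ef, eps = alpha eps0)
  d <- elif_rhs(neuron_state(p$Ef, p$alpha * p$eps0), p)
  expect_equal(unname(d["deps"]), 0)
  # leak current exactly balanced by input
  p2 <- elif_params(Cm = 200, gL = 10, E0 = -65, Eu = -65)
  d2 <- elif_rhs(neuron_state(-55, p2$eps0), p2, I_syn = 0, I_e = 100)
  expect_equal(unname(d2["dV"]), 0)
  # non-finite state is rejected
  expect_error(elif_rhs(neuron_state(NaN, 1), p), "non-finite")
  expect_error(elif_rhs(neuron_state(Inf, 1), p), "non-finite")
})

test_that("madexp_rhs reduces to eLIF form minus w when eps = epsc", {
  p <- madexp_params(a = 2, b = 40, epsc = 0.3, I_KATP = 10)
  s <- neuron_state(-54, p$epsc, w = 7)
  d <- madexp_rhs(s, p, I_e = 50)
  # exponential term has zero prefactor; dV is the eLIF dV minus w/Cm
  de <- elif_rhs(neuron_state(-54, p$epsc), as_elif(p), I_e = 50)
  expect_equal(unname(d["dV"]), unname(de["dV"]) - s$w / p$Cm)
  # energy terms vanish at (V = Ef, eps = alpha eps0, w = 0)
  d0 <- madexp_rhs(neuron_state(p$Ef, p$alpha * p$eps0, 0), p)
  expect_equal(unname(d0["deps"]), 0)
})

test_that("madexp_rhs matches the standard AdExp right-hand side in the
           stated reduction", {
  p <- madexp_params(E0 = -65, Eu = -65, epsc = 0, eps0 = 1, tau_e = 1e12,
                     gamma = 1e12, I_KATP = 0, a = 4, b = 0, tau_w = 100,
                     DeltaT = 2, Vth = -50)
  V <- -56; w <- 3; I <- 80
  d <- madexp_rhs(neuron_state(V, 1, w), p, I_e = I)
  dV_adexp <- (p$gL * (p$E0 - V) +
               p$gL * p$DeltaT * exp((V - p$Vth) / p$DeltaT) - w + I) / p$Cm
  dw_adexp <- (p$a * (V - p$E0) - w) / p$tau_w
  expect_equal(unname(d["dV"]), dV_adexp)
  expect_equal(unname(d["dw"]), dw_adexp)
  expect_lt(abs(d["deps"]), 1e-10)
})

test_that("the exponential overflow guard keeps the flow finite", {
  p <- madexp_params(Vpeak = 0)
  d <- madexp_rhs(neuron_state(-0.001, 1, 0), p)
  expect_true(all(is.finite(d)))
})

test_that("spike_condition implements the energy gate", {
  p <- elif_params(Vth = -50, epsc = 0.2)
  # superthreshold but energy-blocked
  expect_false(spike_condition(neuron_state(-49, p$epsc / 2), p))
  expect_true(spike_condition(neuron_state(p$Vth, 2 * p$epsc), p))
  # ties at eps = epsc count as spiking
  expect_true(spike_condition(neuron_state(p$Vth, p$epsc), p))
  pm <- madexp_params(Vpeak = 0)
  expect_true(spike_condition(neuron_state(pm$Vpeak, 0), pm))
  expect_false(spike_condition(neuron_state(pm$Vth + 1, 1), pm))
})

test_that("apply_reset applies the discontinuous map", {
  p <- elif_params(Vr = -65, delta = 0.05)
  s <- apply_reset(neuron_state(-40, 0.50), p)
  expect_equal(s$V, -65)
  expect_equal(s$eps, 0.45)
  pm <- madexp_params(b = 5, delta = 0.02)
  sm <- apply_reset(neuron_state(0, 0.5, w = 10), pm)
  expect_equal(sm$w, 15)
  # delta = 0 leaves eps unchanged (LIF-limit component)
  p0 <- elif_params(delta = 0)
  expect_equal(apply_reset(neuron_state(-40, 0.7), p0)$eps, 0.7)
})

test_that("parameter invariants are enforced with informative errors", {
  expect_error(elif_params(Cm = 0), "Cm > 0")
  expect_error(elif_params(gL = -1), "gL > 0")
  expect_error(elif_params(alpha = 0), "alpha")
  expect_error(elif_params(alpha = 1.2), "alpha")
  expect_error(elif_params(delta = -0.1), "delta")
  expect_error(elif_params(Ed = -60, Ef = -60), "Ed != Ef")
  expect_warning(elif_params(Ef = -30, Ed = -60), "Ed < Ef")
  # hard-threshold eLIF requires Vr < Vth
  expect_error(elif_params(Vr = -50, Vth = -50), "Vr < Vth")
  # mAdExp allows reset above the soft threshold, but below Vpeak
  expect_silent(p <- madexp_params(Vr = -46, Vth = -50, Vpeak = 0))
  expect_error(madexp_params(Vr = 5, Vpeak = 0), "Vr < Vpeak")
  expect_error(madexp_params(DeltaT = 0), "DeltaT")
  expect_error(madexp_params(Vpeak = -55, Vth = -50), "Vpeak > Vth")
  expect_error(madexp_params(b = -1), "b >= 0")
  expect_error(elif_params(Ef = NA), "finite")
})

test_that("tau_m and update_params behave", {
  p <- elif_params(Cm = 200, gL = 10)
  expect_equal(tau_m(p), 20)
  p2 <- update_params(p, alpha = 0.5, gL = 20)
  expect_equal(p2$alpha, 0.5)
  expect_equal(tau_m(p2), 10)
  expect_s3_class(p2, "elif_params")
  expect_error(update_params(p, nonsense = 1), "nonsense")
  expect_error(update_params(p, alpha = 2), "alpha")
})

test_that("resting_state sits on the healthy energy level", {
  p <- elif_params(alpha = 0.8)
  s <- resting_state(p)
  expect_equal(s$eps, 0.8)
  expect_equal(s$V, effective_leak(0.8, p))
  expect_equal(s$w, 0)
})

test_that("LIF reduction: closed-form voltage under a step current", {
  p <- elif_params(E0 = -65, Eu = -65, delta = 0, epsc = 0, Vth = 100)
  I <- 100
  r <- simulate_neuron(
    p, protocol(400, segments = data.frame(start = 0, stop = 400,
                                           amplitude = I)), dt = 0.01)
  V_cf <- p$E0 + (I / p$gL) * (1 - exp(-r$times / tau_m(p)))
  expect_equal(length(r$spikes), 0L)
  expect_lt(max(abs(r$V - V_cf)), 1e-6)
})

test_that("AdExp reduction: trace matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- madexp_params(E0 = -65, Eu = -65, epsc = 0, tau_e = 1e12,
                     gamma = 1e12, I_KATP = 0, a = 4, b = 0, tau_w = 100,
                     DeltaT = 2, Vth = -50, Vr = -58, Vpeak = 0)
  I <- 120
  rhs <- function(t, y, parms) {
    dV <- (p$gL * (p$E0 - y[1]) +
           p$gL * p$DeltaT * exp((y[1] - p$Vth) / p$DeltaT) - y[2] + I) /
      p$Cm
    dw <- (p$a * (y[1] - p$E0) - y[2]) / p$tau_w
    list(c(dV, dw))
  }
  out <- deSolve::ode(c(V = p$E0, w = 0), seq(0, 1000, by = 0.05), rhs,
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  r <- simulate_neuron(
    p, protocol(1000, segments = data.frame(start = 0, stop = 1000,
                                            amplitude = I)),
    dt = 0.01, record_dt = 0.05)
  expect_equal(length(r$spikes), 0L)
  expect_lt(max(abs(r$V - out[, "V"])), 1e-6)
})
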