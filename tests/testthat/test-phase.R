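test_that("nullclines satisfy their defining equations", {
  p <- elif_params(E0 = -65, Eu = -50, Ef = -62, Ed = -22)
  expect_equal(v_nullcline(p$eps0, p, 0), p$E0)
  expect_equal(v_nullcline(p$eps0, p, p$gL * (p$Eu - p$E0)), p$Eu)
  # negative current shifts towards more negative potentials
  expect_true(all(v_nullcline(c(0, 0.5, 1), p, -40) <
                  v_nullcline(c(0, 0.5, 1), p, 0)))
  expect_equal(eps_nullcline(p$alpha * p$eps0, p), p$Ef)
  expect_equal(eps_nullcline(0, p), p$Ed)
  # inflection of the cubic at eps = alpha eps0
  h <- 1e-4
  d2 <- (eps_nullcline(p$alpha * p$eps0 + h, p) -
         2 * eps_nullcline(p$alpha * p$eps0, p) +
         eps_nullcline(p$alpha * p$eps0 - h, p)) / h^2
  expect_lt(abs(d2), 1e-4)
})

test_that("phase_portrait samples are consistent and rhs vanishes at FPs", {
  cfg <- load_preset("fig3_bistable")
  p <- cfg$model
  pp <- phase_portrait(p)
  expect_equal(pp$v_null, v_nullcline(pp$eps, p, 0))
  expect_equal(pp$eps_null, eps_nullcline(pp$eps, p))
  fp <- pp$fixed_points
  expect_equal(nrow(fp), 3L)
  for (i in seq_len(nrow(fp))) {
    d <- elif_rhs(neuron_state(fp$V[i], fp$eps[i]), p, I_e = 0)
    expect_lt(max(abs(d)), 1e-9)
  }
})

test_that("fixed-point structure: flat nullcline, bistable preset, high I", {
  # Eu = E0: the monotone cubic crosses a constant exactly once
  p1 <- elif_params(E0 = -65, Eu = -65)
  expect_equal(nrow(find_fixed_points(p1)), 1L)
  cfg <- load_preset("fig3_bistable")
  fp <- find_fixed_points(cfg$model)
  expect_equal(nrow(fp), 3L)
  expect_equal(sum(fp$stability == "stable"), 2L)
  expect_equal(sum(fp$stability != "stable"), 1L)
  sn <- saddle_node_currents(cfg$model)
  expect_equal(nrow(find_fixed_points(cfg$model,
                                      I_total = sn["I_plus"] + 5)), 1L)
})

test_that("find_fixed_points agrees with a dense sign-scan oracle", {
  set.seed(7)
  for (k in 1:200) {
    p <- suppressWarnings(random_elif())
    I <- stats::runif(1, -50, 50)
    fp <- find_fixed_points(p, I_total = I)
    roots <- signscan_roots(p, I_total = I)
    expect_equal(nrow(fp), length(roots))
    if (length(roots))
      expect_lt(max(abs(sort(fp$eps) - sort(roots))), 1e-6)
  }
})

test_that("stable fixed points attract, unstable ones repel", {
  p <- load_preset("fig3_bistable")$model
  fp <- find_fixed_points(p)
  for (i in seq_len(nrow(fp))) {
    s0 <- neuron_state(fp$V[i] + 0.5, fp$eps[i] + 0.01)
    r <- simulate_neuron(p, protocol(6000), state0 = s0)
    n <- length(r$V)
    d_end <- abs(r$V[n] - fp$V[i]) + 50 * abs(r$eps[n] - fp$eps[i])
    if (fp$stability[i] == "stable") {
      expect_lt(abs(r$V[n] - fp$V[i]), 0.05)
      expect_lt(abs(r$eps[n] - fp$eps[i]), 0.005)
    } else {
      expect_gt(d_end, 1)
    }
  }
})

test_that("saddle_node_currents brackets the 3-FP interval exactly", {
  p <- load_preset("fig3_bistable")$model
  sn <- saddle_node_currents(p)
  expect_false(attr(sn, "degenerate"))
  expect_lt(sn["I_minus"], sn["I_plus"])
  eps_in <- 0.05 * diff(sn)
  for (I in c(sn["I_minus"] + eps_in, mean(sn), sn["I_plus"] - eps_in))
    expect_equal(nrow(find_fixed_points(p, I_total = I)), 3L)
  for (I in c(sn["I_minus"] - eps_in, sn["I_plus"] + eps_in))
    expect_equal(nrow(find_fixed_points(p, I_total = I)), 1L)
})

test_that("saddle-node interval collapses degenerately at Eu = E0 and
           shrinks with declining health", {
  p0 <- elif_params(E0 = -65, Eu = -65, Ef = -60, Ed = -30)
  sn0 <- saddle_node_currents(p0)
  expect_true(attr(sn0, "degenerate"))
  expect_equal(unname(sn0["I_minus"]), p0$gL * (p0$Ef - p0$E0))
  expect_equal(unname(sn0["I_minus"]), unname(sn0["I_plus"]))
  p <- load_preset("fig3_bistable")$model
  widths <- vapply(c(1, 0.8, 0.6, 0.4), function(a)
    diff(unname(saddle_node_currents(update_params(p, alpha = a)))),
    numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("saddle_node tangency solver matches the reconciled closed form", {
  p <- load_preset("fig3_bistable")$model
  sn <- saddle_node_currents(p)
  cf <- attr(sn, "closed_form")
  expect_equal(as.numeric(sn), as.numeric(cf), tolerance = 1e-8)
})

test_that("rebound_threshold identities hold to machine precision", {
  base <- list(E0 = -65, Ef = -60, Ed = -30, Vth = -50, DeltaT = 2)
  p1 <- do.call(madexp_params, c(base, list(Eu = -65 + 2)))     # = DeltaT
  expect_equal(rebound_threshold(p1)$V_star, p1$Vth)
  p2 <- do.call(madexp_params, c(base, list(Eu = -65 + 2 / exp(1))))
  expect_equal(rebound_threshold(p2)$V_star, p2$Vth - p2$DeltaT)
  p3 <- do.call(madexp_params, c(base, list(Eu = -65 + 4)))     # 2 DeltaT
  expect_false(rebound_threshold(p3)$applicable)
  p4 <- do.call(madexp_params, c(base, list(Eu = -66)))
  expect_true(is.na(rebound_threshold(p4)$V_star))
})

test_that("classify_regime labels the documented cases", {
  p4 <- load_preset("fig4_disease")$model
  expect_equal(classify_regime(p4), "single-rest")
  expect_equal(classify_regime(update_params(p4, alpha = 0.3)),
               "energy-blocked")
  expect_equal(classify_regime(elif_params(E0 = -65, Eu = -65)),
               "single-rest")
})

test_that("alpha_sweep yields the four-stage progression, deterministic", {
  p <- load_preset("fig4_disease")$model
  grid <- seq(1, 0.3, by = -0.01)
  sw <- alpha_sweep(p, grid)
  expect_equal(sw$stages, c("single-rest", "bistable", "tonic-spiking",
                            "energy-blocked"))
  expect_identical(sw$table, alpha_sweep(p, grid)$table)
  # constant regime parameters give a single stage
  p1 <- elif_params(E0 = -65, Eu = -65)
  expect_equal(length(alpha_sweep(p1, grid)$stages), 1L)
  expect_error(alpha_sweep(p, c(1, 0)), "alpha_grid")
})

test_that("alpha_sweep stage boundaries coincide with bifurcation
           conditions", {
  p <- load_preset("fig4_disease")$model
  grid <- seq(1, 0.3, by = -0.01)
  sw <- alpha_sweep(p, grid)
  tab <- sw$table
  # at the single-rest -> bistable boundary, I = 0 enters the SN interval
  i <- max(which(tab$regime == "single-rest"))
  sn_hi <- saddle_node_currents(update_params(p, alpha = tab$alpha[i]))
  sn_lo <- saddle_node_currents(update_params(p, alpha = tab$alpha[i + 1]))
  expect_true(0 < sn_hi["I_minus"] || 0 > sn_hi["I_plus"])
  expect_true(sn_lo["I_minus"] < 0 && 0 < sn_lo["I_plus"])
  # at the tonic -> energy-blocked boundary the FP energy crosses epsc
  j <- max(which(tab$regime == "tonic-spiking"))
  fp_hi <- find_fixed_points(update_params(p, alpha = tab$alpha[j]))
  fp_lo <- find_fixed_points(update_params(p, alpha = tab$alpha[j + 1]))
  expect_gt(fp_hi$eps[1], p$epsc)
  expect_lte(fp_lo$eps[1], p$epsc)
})

test_that("if_curve is type-I-like and collapses at depolarization block", {
  p <- elif_params(E0 = -65, Eu = -65, Ef = -60, Ed = -30, Vth = -50,
                   Vr = -65, delta = 0, epsc = 0, tau_e = 100)
  rheo <- p$gL * (p$Vth - p$E0)
  cur <- if_curve(p, c(rheo - 10, rheo - 1, rheo + 1, rheo + 5, rheo + 20,
                       rheo + 50), T = 1000)
  expect_equal(cur$rate[1:2], c(0, 0))
  expect_true(all(diff(cur$rate[3:6]) > 0))
  expect_lt(cur$rate[3], 15)  # continuous onset: low rate near threshold
  # depleting cell: rate rises with I, then drops to 0 in the block
  p2 <- load_preset("fig3_bistable")$model
  cur2 <- if_curve(p2, c(20, 50, 80), T = 3000)
  expect_equal(cur2$rate[1], 0)
  expect_gt(cur2$rate[2], 0)
  expect_equal(cur2$rate[3], 0)
})
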