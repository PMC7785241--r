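# Shared helpers for the metaneuron test suite. All inputs are generated
# locally (fixture generator or constructed objects); no network access.

.test_env <- new.env(parent = emptyenv())

# fixture bundle, generated once per test run
fixtures <- function() {
  if (is.null(.test_env$fx)) {
    dir <- file.path(tempdir(), "metaneuron-fixtures")
    .test_env$fx <- make_fixtures(dir, seed = 1)
  }
  .test_env$fx
}

cli_script <- function() {
  system.file("cli", "metaneuron.R", package = "metaneuron")
}

# run the CLI; returns list(status, stdout, stderr)
run_cli <- function(...) {
  out <- tempfile(); err <- tempfile()
  status <- system2("Rscript", c(cli_script(), ...),
                    stdout = out, stderr = err)
  list(status = status,
       stdout = if (file.exists(out)) readLines(out, warn = FALSE)
                else character(),
       stderr = if (file.exists(err)) readLines(err, warn = FALSE)
                else character())
}

# construct a minimal simulation_result for feature-extraction tests
fake_result <- function(times, V, eps, spikes, p, w = 0,
                        proto = step_protocol(200, onset = min(times),
                                              offset = max(times))) {
  structure(list(times = times, V = V, eps = eps,
                 w = rep_len(w, length(times)), spikes = spikes,
                 death_time = NA_real_, params = p, protocol = proto,
                 dt = diff(times[1:2]), seed = NULL, method = "rk4"),
            class = "simulation_result")
}

# reference RK4 step of the smooth eLIF flow (for energy accounting checks)
rk4_elif_segment <- function(p, V0, eps0, times, I) {
  n <- length(times)
  V <- numeric(n); eps <- numeric(n)
  V[1] <- V0; eps[1] <- eps0
  f <- function(v, e) {
    s <- neuron_state(v, e)
    elif_rhs(s, p, I_e = I)
  }
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    k1 <- f(V[i], eps[i])
    k2 <- f(V[i] + h / 2 * k1[1], eps[i] + h / 2 * k1[2])
    k3 <- f(V[i] + h / 2 * k2[1], eps[i] + h / 2 * k2[2])
    k4 <- f(V[i] + h * k3[1], eps[i] + h * k3[2])
    V[i + 1] <- V[i] + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    eps[i + 1] <- eps[i] + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  list(V = V, eps = eps)
}

# random valid eLIF parameter set (integrator regime, Ed > Ef)
random_elif <- function() {
  E0 <- stats::runif(1, -75, -60)
  Ef <- stats::runif(1, -66, -55)
  elif_params(Cm = stats::runif(1, 100, 300), gL = stats::runif(1, 5, 20),
              E0 = E0, Eu = E0 + stats::runif(1, 0, 25), Ef = Ef,
              Ed = Ef + stats::runif(1, 10, 45),
              Vth = stats::runif(1, -56, -45),
              Vr = stats::runif(1, -72, -60),
              eps0 = 1, epsc = stats::runif(1, 0, 0.4),
              alpha = stats::runif(1, 0.4, 1),
              tau_e = stats::runif(1, 100, 800),
              delta = stats::runif(1, 0, 0.1))
}

# memoized shipped-network simulations, shared across test files
fig5_sim <- function(alpha, stim = FALSE, seed = 3) {
  key <- paste0("fig5_", alpha, "_", stim, "_", seed)
  if (is.null(.test_env[[key]])) {
    if (is.null(.test_env$fig5_net)) {
      .test_env$fig5_p <- load_preset("fig5_network_neuron")$model
      .test_env$fig5_net <- build_network(network_spec())
    }
    .test_env[[key]] <- simulate_network(.test_env$fig5_net,
                                         .test_env$fig5_p,
                                         alpha = alpha, duration = 5500,
                                         seed = seed, stimulus_on = stim)
  }
  .test_env[[key]]
}

# dense sign-scan root finder used as an oracle for find_fixed_points
signscan_roots <- function(p, I_total = 0, window = c(0, 2), n = 1e5) {
  grid <- seq(window[1], window[2], length.out = n)
  fg <- v_nullcline(grid, p, I_total) - eps_nullcline(grid, p)
  sw <- which(fg[-1] * fg[-n] < 0)
  vapply(sw, function(i)
    stats::uniroot(function(e) v_nullcline(e, p, I_total) -
                     eps_nullcline(e, p),
                   c(grid[i], grid[i + 1]), tol = 1e-13)$root,
    numeric(1))
}
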