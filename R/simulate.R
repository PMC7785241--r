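pack_params <- function(p) {
  base <- c(p$Cm, p$gL, p$E0, p$Eu, p$Ef, p$Ed, p$Vth, p$Vr, p$eps0, p$epsc,
            p$alpha, p$tau_e, p$delta, p$Ie_baseline)
  if (is_madexp(p))
    c(base, p$DeltaT, p$Vpeak, p$a, p$b, p$tau_w, p$gamma, p$I_KATP)
  else
    c(base, 2, 0, 0, 0, 1, 1, 0)  # placeholders, unused for eLIF
}

#' Simulate a single model neuron
#'
#' Fixed-step hybrid integration of the eLIF or mAdExp equations: the smooth
#' flow is advanced with a classical Runge-Kutta (RK4) scheme (or explicit
#' Euler), and at the end of every step the discrete part is applied —
#' spike detection ([spike_condition()]), reset ([apply_reset()]), an
#' optional absolute refractory period, and the death rule. Death is
#' declared when `eps <= 0` while `V >= Ed`; the state is then frozen and
#' no further spikes can be emitted. Spike times are recorded at the
#' end-of-step time (no interpolation), a bias of at most `dt`.
#'
#' The run is deterministic given `(p, state0, proto, dt, seed)`; the seed
#' only matters when the protocol carries Poisson input.
#'
#' @param p an [elif_params()] or [madexp_params()] object.
#' @param proto a [protocol()].
#' @param state0 initial [neuron_state()]; defaults to [resting_state()].
#' @param dt integration step (ms); default 0.05.
#' @param seed integer seed for the Poisson input generator, or `NULL` to
#'   use the current RNG state.
#' @param method `"rk4"` (default) or `"euler"`.
#' @param refractory absolute refractory period after each spike (ms);
#'   the membrane is clamped at `Vr` while energy and adaptation keep
#'   evolving. Default 0.
#' @param record_dt sampling interval of the stored traces (ms); rounded
#'   to a multiple of `dt`. Default: every step.
#' @return an object of class `simulation_result`: list with `times`, `V`,
#'   `eps`, `w` (traces), `spikes` (ms, strictly increasing), `death_time`
#'   (ms or `NA`), and the inputs (`params`, `protocol`, `dt`, `seed`).
#' @examples
#' p <- elif_params()
#' r <- simulate_neuron(p, step_protocol(100, duration = 600), dt = 0.1)
#' length(r$spikes)
#' @export
simulate_neuron <- function(p, proto, state0 = NULL, dt = 0.05, seed = NULL,
                            method = c("rk4", "euler"), refractory = 0,
                            record_dt = dt) {
  stopifnot(inherits(p, "neuron_params"), inherits(proto, "protocol"),
            dt > 0, refractory >= 0)
  method <- match.arg(method)
  if (is.null(state0)) state0 <- resting_state(p)
  stopifnot(inherits(state0, "neuron_state"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  seg <- proto$segments
  if (is.null(seg)) seg <- data.frame(start = numeric(), stop = numeric(),
                                      amplitude = numeric())
  pois <- proto$poisson
  has_pois <- !is.null(pois) && pois$rate > 0 && pois$weight != 0
  asch <- proto$alpha_schedule
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  res <- integrate_neuron_cpp(
    model = as.integer(is_madexp(p)), par = pack_params(p),
    V0 = state0$V, e0 = state0$eps, w0 = state0$w,
    duration = proto$duration, dt = dt,
    seg_start = seg$start, seg_stop = seg$stop, seg_amp = seg$amplitude,
    pois_rate = if (has_pois) pois$rate else 0,
    pois_weight = if (has_pois) pois$weight else 0,
    pois_delta = has_pois && pois$kind == "delta",
    tau_syn = if (has_pois) pois$tau_syn else 2,
    alpha_t = if (is.null(asch)) numeric() else asch$time,
    alpha_v = if (is.null(asch)) numeric() else asch$alpha,
    refractory = refractory, euler = method == "euler",
    rec_every = rec_every)
  structure(list(times = res$t, V = res$V, eps = res$eps, w = res$w,
                 spikes = res$spikes,
                 death_time = if (res$death_time < 0) NA_real_
                              else res$death_time,
                 params = p, protocol = proto, dt = dt, seed = seed,
                 method = method),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation result> %g ms at dt = %g ms (%s): %d spike(s)%s\n",
    x$protocol$duration, x$dt, x$method, length(x$spikes),
    if (is.na(x$death_time)) ""
    else sprintf(", death at %g ms", x$death_time)))
  invisible(x)
}

#' @export
plot.simulation_result <- function(x, spike_display = -50, ...) {
  V <- x$V
  if (length(x$spikes)) {
    idx <- findInterval(x$spikes, x$times)
    V[pmax(idx, 1L)] <- pmax(V[pmax(idx, 1L)], spike_display)
  }
  old <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  plot(x$times, V, type = "l", xlab = "time (ms)", ylab = "V (mV)", ...)
  plot(x$times, x$eps, type = "l", xlab = "time (ms)", ylab = "energy", ...)
  invisible(x)
}

#' Detect depolarization-block intervals
#'
#' Finds maximal intervals of at least `min_duration` in which the membrane
#' sits at a superthreshold/plateau potential with depleted energy
#' (`eps < epsc`) and no spikes: the hallmark of the energy-mediated
#' depolarization block. For eLIF the plateau criterion is `V >= Vth`;
#' for mAdExp, whose spikes overshoot the nominal threshold, it is
#' `V >= V_rest + 2 DeltaT`, with `V_rest` the resting-state potential of
#' the matching eLIF subsystem.
#'
#' @param result a [simulate_neuron()] result.
#' @param p parameter set; defaults to the one stored in `result`.
#' @param min_duration minimal block length to report (ms); default 50.
#' @return data frame with columns `start`, `stop` (ms); zero rows if no
#'   block occurred.
#' @export
detect_depolarization_block <- function(result, p = result$params,
                                        min_duration = 50) {
  t <- result$times
  if (is_madexp(p)) {
    vrest <- tryCatch({
      fp <- find_fixed_points(as_elif(p), I_total = 0)
      if (nrow(fp)) min(fp$V) else effective_leak(p$alpha * p$eps0, p)
    }, error = function(e) effective_leak(p$alpha * p$eps0, p))
    plateau <- result$V >= vrest + 2 * p$DeltaT
  } else {
    plateau <- result$V >= p$Vth
  }
  mask <- plateau & (result$eps < p$epsc)
  # spikes break an interval: blank a sample on each side of every spike
  if (length(result$spikes)) {
    idx <- findInterval(result$spikes, t)
    mask[pmax(idx, 1L)] <- FALSE
    mask[pmin(idx + 1L, length(mask))] <- FALSE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (t[ends] - t[starts]) >= min_duration
  data.frame(start = t[starts[keep]], stop = t[ends[keep]])
}

#' Strip a mAdExp parameter set down to its eLIF subsystem
#'
#' Drops the spike-initiation and adaptation machinery, keeping the shared
#' membrane/energy parameters. Used as the fast approximation for mAdExp
#' resting states.
#'
#' @param p a [madexp_params()] (an `elif_params` passes through).
#' @return an [elif_params()].
#' @export
as_elif <- function(p) {
  if (!is_madexp(p)) return(p)
  elif_params(Cm = p$Cm, gL = p$gL, E0 = p$E0, Eu = p$Eu, Ef = p$Ef,
              Ed = p$Ed, Vth = p$Vth, Vr = p$Vr, eps0 = p$eps0,
              epsc = p$epsc, alpha = p$alpha, tau_e = p$tau_e,
              delta = p$delta, Ie_baseline = p$Ie_baseline)
}
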