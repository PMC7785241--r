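#' Specification of a recurrent E/I network
#'
#' Describes a sparse random network of eLIF neurons with current-based
#' exponential synapses, independent Poisson background drive, an optional
#' stimulus window in which a target subset receives a rate-multiplied
#' drive, and a homeostasis table that maps each energetic-health level
#' `alpha` to compensatory adjustments (excitatory-weight scaling and
#' threshold/reset shifts) that keep the background rate fixed.
#'
#' @param N number of neurons.
#' @param exc_fraction excitatory fraction in `(0, 1)`; the first
#'   `round(N * exc_fraction)` neurons are excitatory.
#' @param density independent edge probability in `(0, 1]`.
#' @param wE,wI synaptic weight magnitudes (pA); inhibitory connections
#'   carry `-wI`.
#' @param delay transmission delay (ms), identical for all edges; must be
#'   at least one integration step.
#' @param tau_syn synaptic current decay time (ms).
#' @param bg_rate background Poisson rate per neuron (Hz).
#' @param bg_weight weight of a background event (pA); defaults to `wE`.
#' @param stimulus `NULL` or list with `n_targets` (stimulated excitatory
#'   neurons, taken from the head of the excitatory population),
#'   `rate_multiplier` and `window` (ms, length 2).
#' @param homeostasis data frame with columns `alpha`, `wE_scale`,
#'   `Vth_shift`, `Vr_shift` (mV); one row per shipped health level.
#' @param seed integer seed for graph construction.
#' @param edge_budget refuse construction above this expected edge count.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(N = 1000, exc_fraction = 0.8, density = 0.1,
                         wE = 10, wI = 120, delay = 1.5, tau_syn = 2,
                         bg_rate = 520, bg_weight = 80,
                         stimulus = list(n_targets = 100,
                                         rate_multiplier = 3,
                                         window = c(1400, 1650)),
                         homeostasis = data.frame(
                           alpha = c(1, 0.85, 0.7), wE_scale = 1,
                           Vth_shift = c(0, 0.35, 0.75),
                           Vr_shift = c(0, 0.35, 0.75)),
                         seed = 42, edge_budget = 5e6) {
  stopifnot(N >= 2, exc_fraction > 0, exc_fraction < 1,
            density > 0, density <= 1, delay > 0, tau_syn > 0,
            bg_rate >= 0)
  if (density * N^2 > edge_budget)
    stop(sprintf("expected edge count %.3g exceeds the budget %.3g",
                 density * N^2, edge_budget), call. = FALSE)
  if (!is.null(stimulus))
    stopifnot(stimulus$n_targets <= round(N * exc_fraction),
              length(stimulus$window) == 2)
  stopifnot(all(c("alpha", "wE_scale", "Vth_shift", "Vr_shift") %in%
                names(homeostasis)))
  structure(list(N = N, exc_fraction = exc_fraction, density = density,
                 wE = wE, wI = wI, delay = delay, tau_syn = tau_syn,
                 bg_rate = bg_rate, bg_weight = bg_weight,
                 stimulus = stimulus, homeostasis = homeostasis,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Build the network instance
#'
#' Draws a directed Erdos-Renyi graph (independent edge probability =
#' `density`, no self-loops) reproducibly from the spec's seed and stores
#' it in compressed sparse row form with signed weights: `wE` from
#' excitatory sources, `-wI` from inhibitory ones.
#'
#' @param spec a [network_spec()].
#' @return object of class `elif_network`: list with the spec, `n_exc`,
#'   and CSR fields `ptr` (0-based offsets), `idx` (0-based targets),
#'   `weights`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  N <- spec$N
  n_exc <- round(N * spec$exc_fraction)
  targets <- vector("list", N)
  for (i in seq_len(N)) {
    tg <- which(stats::runif(N) < spec$density)
    targets[[i]] <- tg[tg != i]
  }
  deg <- lengths(targets)
  ptr <- c(0L, cumsum(deg))
  idx <- unlist(targets, use.names = FALSE) - 1L
  w <- rep(ifelse(seq_len(N) <= n_exc, spec$wE, -spec$wI), deg)
  structure(list(spec = spec, n_exc = n_exc, ptr = as.integer(ptr),
                 idx = as.integer(idx), weights = as.numeric(w)),
            class = "elif_network")
}

#' @export
print.elif_network <- function(x, ...) {
  cat(sprintf("<eLIF network> N = %d (%d exc), %d edges, density %.3g\n",
              x$spec$N, x$n_exc, length(x$idx), x$spec$density))
  invisible(x)
}

#' Simulate a recurrent eLIF network
#'
#' Synchronous clock-driven (Euler) update of all neurons with delayed
#' current-based synaptic events and independent Poisson background
#' generators. All neurons share one parameter set, modified by the
#' homeostasis-table row for the requested `alpha`: `Vth` and `Vr` are
#' shifted and the excitatory weights (recurrent and background) scaled.
#' The stimulus window of the spec multiplies the background rate of the
#' first `n_targets` excitatory neurons.
#'
#' @param net a [build_network()] result.
#' @param p an [elif_params()] object (shared by all neurons).
#' @param alpha energetic-health level; must match a homeostasis-table row.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param seed integer seed for the Poisson generators.
#' @param stimulus_on whether to apply the spec's stimulus window.
#' @param refractory absolute refractory period (ms).
#' @param record_idx 1-based neuron indices whose traces to record.
#' @param record_dt trace sampling interval (ms).
#' @return object of class `network_result`: list with `spike_trains`
#'   (list of N numeric vectors, ms), `params` (the adjusted parameter
#'   set), `alpha`, `duration`, `n_dead` and optional `traces`.
#' @export
simulate_network <- function(net, p, alpha = 1, duration = 5500, dt = 0.05,
                             seed = 1, stimulus_on = FALSE, refractory = 2,
                             record_idx = integer(), record_dt = 1) {
  stopifnot(inherits(net, "elif_network"), inherits(p, "elif_params"),
            !is_madexp(p))
  spec <- net$spec
  hrow <- spec$homeostasis[match(alpha, spec$homeostasis$alpha), ]
  if (any(is.na(hrow)))
    stop("alpha = ", alpha, " has no homeostasis-table entry", call. = FALSE)
  padj <- update_params(p, alpha = alpha,
                        Vth = p$Vth + hrow$Vth_shift,
                        Vr = p$Vr + hrow$Vr_shift)
  w <- net$weights
  w[w > 0] <- w[w > 0] * hrow$wE_scale
  bg_w <- spec$bg_weight * hrow$wE_scale
  stopifnot(spec$delay >= dt)
  stim <- spec$stimulus
  has_stim <- stimulus_on && !is.null(stim)
  stim_idx <- if (has_stim) seq_len(stim$n_targets) - 1L else integer()
  set.seed(as.integer(seed))
  eps_init <- padj$alpha * padj$eps0
  V_init <- effective_leak(eps_init, padj) +
    stats::runif(spec$N, 0, padj$Vth - effective_leak(eps_init, padj))
  res <- simulate_network_cpp(
    par = pack_params(padj), ptr = net$ptr, idx = net$idx, wsyn = w,
    V0 = V_init, e0 = rep(eps_init, spec$N),
    duration = duration, dt = dt,
    delay_steps = max(1L, as.integer(round(spec$delay / dt))),
    tau_syn = spec$tau_syn, bg_rate = spec$bg_rate, bg_weight = bg_w,
    stim_idx = as.integer(stim_idx),
    stim_mult = if (has_stim) stim$rate_multiplier else 1,
    stim_start = if (has_stim) stim$window[1] else 0,
    stim_stop = if (has_stim) stim$window[2] else 0,
    refractory = refractory, rec_idx = as.integer(record_idx) - 1L,
    rec_every = max(1L, as.integer(round(record_dt / dt))))
  structure(list(spike_trains = res$spikes, params = padj, alpha = alpha,
                 duration = duration, dt = dt, seed = seed,
                 n_dead = res$n_dead,
                 traces = if (length(record_idx))
                   list(t = res$t, V = res$V, eps = res$eps) else NULL,
                 spec = spec),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  n_active <- sum(lengths(x$spike_trains) > 0)
  cat(sprintf(
    "<network result> N = %d, alpha = %g, %g ms: %d spikes, %d active, %d dead\n",
    length(x$spike_trains), x$alpha, x$duration,
    sum(lengths(x$spike_trains)), n_active, x$n_dead))
  invisible(x)
}

#' Spike-train statistics of a network simulation
#'
#' Per-neuron firing rates over the analysis window, per-neuron ISI
#' coefficients of variation (neurons with at least `min_spikes` spikes),
#' and the mean pairwise Pearson cross-correlation of spike counts binned
#' at `bin` ms over a seeded random subsample of neuron pairs. The
#' asynchronous-irregular (AI) label requires mean CC below `1/N` and mean
#' CV within `[0.5, 1.2]`.
#'
#' @param trains list of spike-time vectors (ms) or a `network_result`.
#' @param window analysis window (ms, length 2).
#' @param bin CC bin width (ms).
#' @param n_pairs number of sampled pairs for the CC estimate, or `Inf`
#'   (the default) for the exact mean over all distinct pairs, computed by
#'   one matrix product. Subsampling is kept as an option for very large
#'   networks; note that with a few thousand pairs the subsampling noise
#'   (about 1/sqrt(n_bins * n_pairs)) is comparable to the `1/N` bound the
#'   AI criterion tests.
#' @param min_spikes minimal spike count for a CV entry.
#' @param seed seed for the pair subsample (the caller's RNG state is
#'   preserved).
#' @return object of class `network_stats`: list with `rates` (Hz), `cv`,
#'   (`NA` where undefined), `mean_cv`, `median_rate`, `mean_cc`,
#'   `ai_state`, `window`, `n`.
#' @export
compute_network_stats <- function(trains, window = c(500, 5500), bin = 5,
                                  n_pairs = Inf, min_spikes = 5,
                                  seed = 1) {
  if (inherits(trains, "network_result")) trains <- trains$spike_trains
  N <- length(trains)
  wlen <- diff(window) / 1e3  # s
  clip <- lapply(trains, function(s) s[s > window[1] & s <= window[2]])
  counts <- lengths(clip)
  rates <- counts / wlen
  cv <- vapply(clip, function(s) {
    if (length(s) < max(min_spikes, 2)) return(NA_real_)
    isi <- diff(s)
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  # binned spike counts for the correlation estimate
  breaks <- seq(window[1], window[2], by = bin)
  nb <- length(breaks) - 1L
  bc <- vapply(clip, function(s)
    tabulate(findInterval(s, breaks, left.open = TRUE,
                          rightmost.closed = TRUE), nbins = nb),
    integer(nb))
  active <- which(apply(bc, 2, stats::sd) > 0)
  mean_cc <- NA_real_
  if (length(active) >= 2) {
    if (is.finite(n_pairs)) {
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(as.integer(seed))
      i <- sample(active, n_pairs, replace = TRUE)
      j <- sample(active, n_pairs, replace = TRUE)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      ok <- i != j
      ccs <- mapply(function(a, b) stats::cor(bc[, a], bc[, b]),
                    i[ok], j[ok])
      mean_cc <- mean(ccs, na.rm = TRUE)
    } else {
      cm <- stats::cor(bc[, active])
      mean_cc <- mean(cm[upper.tri(cm)])
    }
  }
  mean_cv <- mean(cv, na.rm = TRUE)
  structure(list(rates = rates, cv = cv, mean_cv = mean_cv,
                 median_rate = stats::median(rates), mean_cc = mean_cc,
                 ai_state = is.finite(mean_cc) && mean_cc < 1 / N &&
                   is.finite(mean_cv) && mean_cv >= 0.5 && mean_cv <= 1.2,
                 window = window, n = N),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "<network stats> median rate %.3g Hz, mean CV %.3g, mean CC %.3g (1/N = %.3g)%s\n",
    x$median_rate, x$mean_cv, x$mean_cc, 1 / x$n,
    if (x$ai_state) " [AI]" else ""))
  invisible(x)
}

#' Burst/tonic profile of the stimulus response
#'
#' Characterises the response of the stimulated subset during the stimulus
#' window: the fraction of time the population rate exceeds `k` times the
#' background rate, the number of distinct supra-threshold bursts (runs of
#' consecutive bins, merged across gaps of at most one bin), and the mean
#' within-burst population rate.
#'
#' @param trains list of spike trains or a `network_result`.
#' @param targets 1-based indices of the stimulated subset.
#' @param window stimulus window (ms, length 2).
#' @param background_window window defining the background rate (ms).
#' @param bin bin width (ms).
#' @param k burst threshold as a multiple of the background rate.
#' @return list with `burst_count`, `time_fraction_active`,
#'   `mean_burst_rate` (Hz per neuron), `background_rate` (Hz per neuron).
#' @export
stimulus_response_profile <- function(trains, targets, window,
                                      background_window = c(500, window[1]),
                                      bin = 10, k = 3) {
  if (inherits(trains, "network_result")) trains <- trains$spike_trains
  sub <- trains[targets]
  n <- length(targets)
  bg_len <- diff(background_window) / 1e3
  bg_rate <- sum(vapply(sub, function(s)
    sum(s > background_window[1] & s <= background_window[2]),
    numeric(1))) / n / bg_len
  breaks <- seq(window[1], window[2], by = bin)
  nb <- length(breaks) - 1L
  if (nb < 1) stop("stimulus window shorter than one bin", call. = FALSE)
  pooled <- sort(unlist(lapply(sub, function(s)
    s[s > window[1] & s <= window[2]])))
  counts <- tabulate(findInterval(pooled, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE), nbins = nb)
  rate_bins <- counts / n / (bin / 1e3)  # Hz per neuron
  active <- rate_bins > k * max(bg_rate, 1e-9)
  # merge across single-bin gaps so a burst briefly dipping is one burst
  merged <- active
  if (nb >= 3)
    for (i in 2:(nb - 1))
      if (!active[i] && active[i - 1] && active[i + 1]) merged[i] <- TRUE
  r <- rle(merged)
  burst_count <- sum(r$values)
  list(burst_count = burst_count,
       time_fraction_active = mean(active),
       mean_burst_rate = if (any(active)) mean(rate_bins[active])
                         else 0,
       background_rate = bg_rate)
}
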