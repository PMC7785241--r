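#' Default thresholds for the behavior classifier
#'
#' The classifier is a pure function of extracted features; these knobs
#' define its decision boundaries. Defaults: adaptation index 0.1, delayed
#' onset at 30% of the step, sag ratio 0.05, rebound window 300 ms,
#' burstiness (intra/inter median ISI ratio from a 2-means split of the
#' log-ISIs) below 0.5 marks bursting, inter-burst gap regularity split at
#' a coefficient of variation of 0.25.
#'
#' @param adaptation adaptation-index threshold.
#' @param latency_frac delayed-onset fraction of the step duration.
#' @param sag sag-ratio threshold.
#' @param rebound_window post-offset window for rebound spikes (ms).
#' @param burstiness intra/inter ISI ratio below which a train is bursty.
#' @param gap_cv inter-burst gap CV separating regular from intermittent.
#' @param block_min minimal depolarization-block duration (ms).
#' @return named list of thresholds.
#' @export
behavior_thresholds <- function(adaptation = 0.1, latency_frac = 0.3,
                                sag = 0.05, rebound_window = 300,
                                burstiness = 0.5, gap_cv = 0.25,
                                block_min = 50) {
  list(adaptation = adaptation, latency_frac = latency_frac, sag = sag,
       rebound_window = rebound_window, burstiness = burstiness,
       gap_cv = gap_cv, block_min = block_min)
}

principal_step <- function(proto) {
  seg <- proto$segments
  if (is.null(seg) || !nrow(seg))
    stop("protocol has no step segment", call. = FALSE)
  seg[which.max(abs(seg$amplitude)), ]
}

# 2-means split of log-ISIs; returns burstiness ratio and the gap indices
split_isi <- function(isi) {
  if (length(isi) < 4 || max(isi) / min(isi) < 1.5)
    return(list(burstiness = 1, gaps = integer()))
  lx <- log(isi)
  cent <- matrix(c(min(lx), max(lx)), ncol = 1)
  km <- suppressWarnings(stats::kmeans(matrix(lx, ncol = 1), centers = cent))
  hi <- which.max(km$centers)
  intra <- isi[km$cluster != hi]
  inter <- isi[km$cluster == hi]
  if (!length(intra) || !length(inter))
    return(list(burstiness = 1, gaps = integer()))
  list(burstiness = stats::median(intra) / stats::median(inter),
       gaps = which(km$cluster == hi))
}

#' Extract electrophysiological features from a step response
#'
#' Computes the feature set consumed by [classify_behavior()]: first-spike
#' latency, the inter-spike-interval (ISI) sequence during the step, the
#' adaptation index `(last ISI - first ISI)/(last ISI + first ISI)`, a
#' burstiness index from a 2-means split of the log-ISIs, the sag ratio
#' `(V_min - V_steady)/(V_min - V_baseline)` on hyperpolarizing steps, and
#' the number of rebound spikes in a post-offset window. ISI-based features
#' are `NA` when fewer than two step spikes were emitted.
#'
#' @param result a [simulate_neuron()] result.
#' @param proto the [protocol()] used; must contain one principal step.
#' @param thresholds a [behavior_thresholds()] list.
#' @return named list of features (class `behavior_features`).
#' @export
extract_features <- function(result, proto = result$protocol,
                             thresholds = behavior_thresholds()) {
  p <- result$params
  step <- principal_step(proto)
  onset <- step$start; offset <- step$stop
  dur <- offset - onset
  t <- result$times
  sp <- result$spikes
  during <- sp[sp > onset & sp <= offset]
  after <- sp[sp > offset & sp <= offset + thresholds$rebound_window]
  isi <- diff(during)
  adaptation <- if (length(isi) >= 2)
    (isi[length(isi)] - isi[1]) / (isi[length(isi)] + isi[1]) else NA_real_
  bs <- split_isi(isi)
  # burst segmentation from the gap ISIs
  n_bursts <- if (length(bs$gaps)) length(bs$gaps) + 1L
              else if (length(during)) 1L else 0L
  gap_lengths <- isi[bs$gaps]
  gap_cv <- if (length(gap_lengths) >= 2)
    stats::sd(gap_lengths) / mean(gap_lengths) else NA_real_
  # initial-burst signature: the slow (inter) ISIs form one contiguous
  # suffix -- a fast onset burst followed by slower tonic firing to the end
  gap_suffix <- length(bs$gaps) >= 2 && all(diff(bs$gaps) == 1L) &&
    bs$gaps[length(bs$gaps)] == length(isi)
  tail_cv <- if (gap_suffix) {
    rest <- isi[bs$gaps]
    # drop the burst-to-tonic transition interval when enough tail remains
    if (length(rest) >= 3) rest <- rest[-1]
    stats::sd(rest) / mean(rest)
  } else NA_real_
  first_gap_at <- if (length(bs$gaps)) bs$gaps[1] else NA_integer_
  # sag on hyperpolarizing steps
  sag <- NA_real_
  if (step$amplitude < 0) {
    base_idx <- t < onset
    in_idx <- t >= onset & t < offset
    if (any(base_idx) && any(in_idx)) {
      Vb <- stats::median(result$V[base_idx])
      Vmin <- min(result$V[in_idx])
      steady_idx <- t >= offset - 0.2 * dur & t < offset
      Vs <- mean(result$V[steady_idx])
      sag <- if (abs(Vmin - Vb) < 1e-9) 0 else (Vmin - Vs) / (Vmin - Vb)
    }
  }
  # end-of-step membrane/energy context
  i_off <- max(which(t <= offset))
  subthr_end <- result$V[i_off] < p$Vth
  tail_idx <- which(t > (if (length(during)) max(during) else onset) &
                    t <= offset)
  eps_recovering <- length(tail_idx) >= 2 &&
    result$eps[tail_idx[length(tail_idx)]] > result$eps[tail_idx[1]]
  med_isi <- if (length(isi)) stats::median(isi) else NA_real_
  spiked_to_end <- length(during) > 0 &&
    (offset - max(during)) <= max(3 * med_isi, 0.15 * dur, na.rm = TRUE)
  blocks <- detect_depolarization_block(result, p,
                                        min_duration = thresholds$block_min)
  blocks <- blocks[blocks$stop > onset & blocks$start < offset, ,
                   drop = FALSE]
  structure(list(
    step_amplitude = step$amplitude, onset = onset, offset = offset,
    n_spikes_step = length(during), n_spikes_total = length(sp),
    latency = if (length(during)) during[1] - onset else NA_real_,
    latency_frac = if (length(during)) (during[1] - onset) / dur
                   else NA_real_,
    isi = isi, adaptation_index = adaptation,
    burstiness = bs$burstiness, n_bursts = n_bursts, gap_cv = gap_cv,
    gap_suffix = gap_suffix, tail_cv = tail_cv, first_gap_at = first_gap_at,
    sag_ratio = sag, rebound_count = length(after),
    subthreshold_at_offset = subthr_end, eps_recovering = eps_recovering,
    spiked_to_end = spiked_to_end, block_intervals = blocks,
    dead = !is.na(result$death_time)),
    class = "behavior_features")
}

#' Classify a step response into a behavior label
#'
#' Maps extracted features onto the qualitative behavior repertoire:
#' regular spiking (RS), adaptive spiking (AS), initial burst (IB), regular
#' bursting (RB), transient spiking (TS), delayed bursting (DB), delayed
#' accelerating (DA), post-inhibitory rebound (IR), post-excitatory rebound
#' (ER), intermittent spiking (IS), plus `depol-block` (superthreshold
#' silence with depleted energy) and `silent`. Rule priority:
#' depol-block > rebound labels > delayed labels > transient > burst
#' labels > AS > RS; ambiguous cases carry secondary candidates in the
#' `secondary` field.
#'
#' @param features a [extract_features()] result, or a
#'   [simulate_neuron()] result (features are then extracted first).
#' @param proto protocol, when `features` is a simulation result.
#' @param thresholds a [behavior_thresholds()] list.
#' @return object of class `behavior_report`: list with `label`,
#'   `secondary` (character vector) and `features`.
#' @export
classify_behavior <- function(features, proto = NULL,
                              thresholds = behavior_thresholds()) {
  if (inherits(features, "simulation_result"))
    features <- extract_features(features,
                                 if (is.null(proto)) features$protocol
                                 else proto, thresholds)
  f <- features
  th <- thresholds
  secondary <- character()
  hyper <- f$step_amplitude < 0
  bursty <- is.finite(f$burstiness) && f$burstiness < th$burstiness

  label <- if (nrow(f$block_intervals) > 0) {
    if (f$n_spikes_step > 0) secondary <- c(secondary, "TS")
    "depol-block"
  } else if (hyper && f$n_spikes_step == 0 && f$rebound_count > 0) {
    "IR"
  } else if (!hyper && f$n_spikes_step == 0 && f$rebound_count > 0) {
    "ER"
  } else if (f$n_spikes_step == 0) {
    "silent"
  } else if (is.finite(f$latency_frac) && f$latency_frac > th$latency_frac &&
             f$n_spikes_step >= 2) {
    if (bursty) "DB"
    else if (is.finite(f$adaptation_index) &&
             f$adaptation_index < -th$adaptation / 2) "DA"
    else { secondary <- c(secondary, "DA"); "DB" }
  } else if (!f$spiked_to_end && f$subthreshold_at_offset &&
             f$eps_recovering && !bursty) {
    "TS"
  } else if (bursty) {
    if (f$gap_suffix && f$first_gap_at >= 2 && is.finite(f$tail_cv) &&
        f$tail_cv < 0.2 && f$spiked_to_end) "IB"
    else if (f$n_bursts >= 3 && is.finite(f$gap_cv) && f$gap_cv > th$gap_cv) "IS"
    else "RB"
  } else if (is.finite(f$adaptation_index) &&
             f$adaptation_index > th$adaptation) {
    "AS"
  } else {
    "RS"
  }
  structure(list(label = label, secondary = unique(secondary),
                 features = f), class = "behavior_report")
}

#' @export
print.behavior_report <- function(x, ...) {
  cat(sprintf("<behavior> %s%s  (%d step spikes, adaptation %.3g, burstiness %.3g, rebound %d)\n",
              x$label,
              if (length(x$secondary))
                paste0(" [", paste(x$secondary, collapse = ","), "]") else "",
              x$features$n_spikes_step,
              x$features$adaptation_index, x$features$burstiness,
              x$features$rebound_count))
  invisible(x)
}

#' Discriminate sag-mediated from energy-mediated rebound
#'
#' Combines the rebound spike count with the sag ratio to tell the
#' adaptation-driven (AdExp-style, sag-associated) rebound from the
#' energy-mediated rebound, which needs no sag and exists when the rebound
#' bifurcation applies (`0 < Eu - E0 < DeltaT`, see [rebound_threshold()]).
#'
#' @param p a [madexp_params()] object.
#' @param result a [simulate_neuron()] result under a hyperpolarizing
#'   protocol.
#' @param proto the protocol (defaults to the one stored in `result`).
#' @param thresholds a [behavior_thresholds()] list.
#' @return one of `"sag-rebound"`, `"no-sag-rebound"`, `"none"`.
#' @export
rebound_mode <- function(p, result, proto = result$protocol,
                         thresholds = behavior_thresholds()) {
  f <- extract_features(result, proto, thresholds)
  if (f$step_amplitude >= 0)
    stop("rebound_mode expects a hyperpolarizing protocol", call. = FALSE)
  if (f$rebound_count == 0) return("none")
  if (is.finite(f$sag_ratio) && f$sag_ratio > thresholds$sag)
    return("sag-rebound")
  # energy-mediated rebound: either the rebound bifurcation proper
  # (0 < Eu - E0 < DeltaT) or the resonator regime (Eu < E0), where the
  # energy overshoot after release raises the leak potential above rest
  energy_mech <- isTRUE(rebound_threshold(p)$applicable) || p$Eu < p$E0
  adapt_mech <- p$a > 0 || p$b > 0
  if (energy_mech || adapt_mech) "no-sag-rebound" else "none"
}
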