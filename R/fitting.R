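#' Current-clamp sweep set
#'
#' Container for subthreshold feature extraction: a list of sweeps, each a
#' data frame with uniformly sampled columns `t` (ms), `V` (mV) and `I`
#' (pA, the injected current). Step onset/offset and the baseline window
#' are detected from the current trace (the baseline is where `I` equals
#' its pre-step value).
#'
#' @param sweeps a list of data frames with columns `t`, `V`, `I`, or one
#'   data frame with an additional `sweep` column.
#' @return object of class `sweep_set`: the sweep list plus per-sweep step
#'   metadata (`onset`, `offset`, `amplitude`).
#' @export
sweep_set <- function(sweeps) {
  if (is.data.frame(sweeps)) {
    stopifnot("sweep" %in% names(sweeps))
    sweeps <- split(sweeps[c("t", "V", "I")], sweeps$sweep)
  }
  sweeps <- lapply(sweeps, function(s) {
    s <- as.data.frame(s)
    if (!all(c("t", "V", "I") %in% names(s)))
      stop("each sweep needs columns t, V, I", call. = FALSE)
    dtv <- diff(s$t)
    if (max(abs(dtv - dtv[1])) > 1e-6 * dtv[1])
      stop("sweep sampling must be uniform", call. = FALSE)
    s
  })
  meta <- lapply(sweeps, function(s) {
    i0 <- s$I[1]
    on_idx <- which(abs(s$I - i0) > 1e-9)
    if (!length(on_idx))
      return(list(onset = NA_real_, offset = NA_real_, amplitude = 0))
    list(onset = s$t[on_idx[1]], offset = s$t[on_idx[length(on_idx)]],
         amplitude = s$I[on_idx[1]] - i0)
  })
  structure(list(sweeps = sweeps, meta = meta), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  amps <- vapply(x$meta, `[[`, numeric(1), "amplitude")
  cat(sprintf("<sweep set> %d sweep(s), step amplitudes: %s pA\n",
              length(x$sweeps), paste(signif(amps, 3), collapse = ", ")))
  invisible(x)
}

baseline_samples <- function(ss) {
  unlist(mapply(function(s, m) {
    if (is.na(m$onset)) s$V else s$V[s$t < m$onset]
  }, ss$sweeps, ss$meta, SIMPLIFY = FALSE))
}

#' Estimate the resting leak potential from sweep baselines
#'
#' Median of the voltage samples pooled over all pre-step baseline windows.
#' For a model-generated sweep set this recovers the effective leak
#' potential at the resting energy level.
#'
#' @param ss a [sweep_set()].
#' @return estimated resting potential (mV).
#' @export
estimate_EL <- function(ss) {
  v <- baseline_samples(ss)
  if (!length(v)) stop("no baseline samples before the step", call. = FALSE)
  stats::median(v)
}

#' Estimate the membrane time constant from hyperpolarizing onsets
#'
#' For each hyperpolarizing sweep, estimates the initial slope of the
#' response over the initial-slope window (the larger of 5 ms and 5% of
#' the step duration after onset) and divides the steady-state deflection
#' by it. A straight-line fit over a finite window systematically
#' underestimates the onset slope of an exponential (by roughly
#' `T/(2 tau_m)`), so the slope is obtained by fitting the RC charging
#' curve `V = base + dV (1 - exp(-t/tau))` to the window samples, which
#' returns `Cm/gL` exactly for a pure RC response. Sweeps whose onset is
#' non-monotonic (noise-dominated) are dropped with a warning.
#'
#' @param ss a [sweep_set()].
#' @param slope_window `NULL` for the default window rule, or a fixed
#'   window length (ms).
#' @return estimated membrane time constant (ms), averaged over usable
#'   hyperpolarizing sweeps.
#' @export
estimate_tau_m <- function(ss, slope_window = NULL) {
  est <- c()
  for (k in seq_along(ss$sweeps)) {
    m <- ss$meta[[k]]
    if (is.na(m$onset) || m$amplitude >= 0) next
    s <- ss$sweeps[[k]]
    dur <- m$offset - m$onset
    win <- if (is.null(slope_window)) max(5, 0.05 * dur) else slope_window
    idx <- which(s$t >= m$onset & s$t <= m$onset + win)
    if (length(idx) < 3) next
    base <- stats::median(s$V[s$t < m$onset])
    fit <- stats::lm(V ~ t, data = s[idx, ])
    slope <- coef(fit)[["t"]]
    steady_idx <- s$t >= m$offset - 0.2 * dur & s$t < m$offset
    dV <- mean(s$V[steady_idx]) - base
    if (slope >= 0 || dV >= 0) {
      warning("non-monotonic hyperpolarizing onset in sweep ", k,
              "; skipped", call. = FALSE)
      next
    }
    # onset slope from the RC charging curve over the window (a straight
    # line over a finite window is biased low by ~ win/(2 tau_m))
    tj <- s$t[idx] - m$onset
    vj <- s$V[idx]
    sse <- function(log_tau) {
      pred <- base + dV * (1 - exp(-tj / exp(log_tau)))
      sum((vj - pred)^2)
    }
    est <- c(est, exp(stats::optimize(sse, log(c(0.05, 1e4)))$minimum))
  }
  if (!length(est))
    stop("no usable hyperpolarizing sweep", call. = FALSE)
  mean(est)
}

#' Estimate the total subthreshold conductance gL + a
#'
#' Least-squares regression of the steady-state deflection
#' `dV = E_ss - E_L` against the injected current over the subthreshold
#' depolarizing sweeps; the slope is `1/(gL + a)`, so the reciprocal is
#' returned (nS).
#'
#' @param ss a [sweep_set()] with at least two depolarizing sweeps at
#'   distinct currents.
#' @return estimated `gL + a` (nS).
#' @export
estimate_gL_plus_a <- function(ss) {
  EL <- estimate_EL(ss)
  rows <- list()
  for (k in seq_along(ss$sweeps)) {
    m <- ss$meta[[k]]
    if (is.na(m$onset) || m$amplitude <= 0) next
    s <- ss$sweeps[[k]]
    dur <- m$offset - m$onset
    steady_idx <- s$t >= m$offset - 0.2 * dur & s$t < m$offset
    rows[[length(rows) + 1]] <- data.frame(I = m$amplitude,
                                           dV = mean(s$V[steady_idx]) - EL)
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || length(unique(d$I)) < 2)
    stop("need >= 2 depolarizing sweeps at distinct currents",
         call. = FALSE)
  slope <- coef(stats::lm(dV ~ I, data = d))[["I"]]
  if (slope <= 0) stop("non-positive dV/I slope", call. = FALSE)
  1 / slope
}

#' Subthreshold feature report
#'
#' Bundles the three estimators: resting potential, membrane time constant
#' and total subthreshold conductance, plus the per-sweep steady-state
#' deflections.
#'
#' @param ss a [sweep_set()].
#' @return object of class `subthreshold_features`: list with `EL_hat`
#'   (mV), `tau_m_hat` (ms), `gL_plus_a_hat` (nS), `deflections` (mV per
#'   sweep).
#' @export
subthreshold_features <- function(ss) {
  EL <- estimate_EL(ss)
  defl <- vapply(seq_along(ss$sweeps), function(k) {
    m <- ss$meta[[k]]
    if (is.na(m$onset)) return(NA_real_)
    s <- ss$sweeps[[k]]
    dur <- m$offset - m$onset
    steady_idx <- s$t >= m$offset - 0.2 * dur & s$t < m$offset
    mean(s$V[steady_idx]) - EL
  }, numeric(1))
  structure(list(EL_hat = EL, tau_m_hat = estimate_tau_m(ss),
                 gL_plus_a_hat = estimate_gL_plus_a(ss),
                 deflections = defl),
            class = "subthreshold_features")
}

#' @export
print.subthreshold_features <- function(x, ...) {
  cat(sprintf(
    "<subthreshold features> EL = %.4g mV, tau_m = %.4g ms, gL + a = %.4g nS\n",
    x$EL_hat, x$tau_m_hat, x$gL_plus_a_hat))
  invisible(x)
}

#' Discrepancy between a simulation and a target recording
#'
#' Weighted sum of (i) the subthreshold root-mean-square voltage error with
#' samples within `spike_mask` ms of any spike (in either trace) masked
#' out, (ii) the absolute spike-count difference, and (iii) the mean
#' absolute time difference over greedily matched spike pairs (nearest
#' neighbours, each difference capped at `time_cap` ms). A result compared
#' against itself scores exactly 0. The score is meant as an objective for
#' externally driven parameter tuning; no optimizer is bundled.
#'
#' @param result a [simulate_neuron()] result.
#' @param target list with fields `t` (ms), `V` (mV) and `spikes` (ms) —
#'   e.g. another simulation result or a recorded sweep.
#' @param weights named numeric: cost per mV of RMSE, per missing/extra
#'   spike, and per ms of matched spike-time difference.
#' @param spike_mask half-width of the mask around spikes (ms).
#' @param time_cap cap on each matched spike-time difference (ms).
#' @return non-negative discrepancy score (dimensionless).
#' @export
discrepancy <- function(result, target,
                        weights = c(rmse = 1, count = 10, time = 0.1),
                        spike_mask = 5, time_cap = 50) {
  tt <- target$t %||% target$times
  tv <- target$V
  tsp <- target$spikes %||% numeric()
  v <- stats::approx(result$times, result$V, xout = tt, rule = 2)$y
  mask <- rep(TRUE, length(tt))
  for (s in c(result$spikes, tsp))
    mask[abs(tt - s) <= spike_mask] <- FALSE
  rmse <- if (any(mask)) sqrt(mean((v[mask] - tv[mask])^2)) else 0
  n1 <- length(result$spikes); n2 <- length(tsp)
  dcount <- abs(n1 - n2)
  tdiff <- 0
  if (n1 && n2) {
    a <- result$spikes; b <- tsp
    matched <- c()
    for (s in a[seq_len(min(n1, n2))]) {
      jj <- which.min(abs(b - s))
      matched <- c(matched, min(abs(b[jj] - s), time_cap))
      b <- b[-jj]
      if (!length(b)) break
    }
    tdiff <- mean(matched)
  }
  unname(weights["rmse"] * rmse + weights["count"] * dcount +
         weights["time"] * tdiff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write sweep files
#'
#' Plain tabular text with columns `t_ms`, `V_mV`, `I_pA` (and `sweep` when
#' several sweeps share one file); header metadata lines are prefixed
#' with `#`.
#'
#' @param ss a [sweep_set()] (for writing).
#' @param path file path.
#' @param header named character vector of metadata to embed.
#' @return `read_sweeps` returns a [sweep_set()]; `write_sweeps` returns
#'   `path` invisibly.
#' @export
write_sweeps <- function(ss, path, header = character()) {
  d <- do.call(rbind, lapply(seq_along(ss$sweeps), function(k)
    cbind(sweep = k, ss$sweeps[[k]])))
  names(d) <- c("sweep", "t_ms", "V_mV", "I_pA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# metaneuron sweep set (%d sweeps)",
                       length(ss$sweeps)),
               sprintf("# %s: %s", names(header), header)), con)
  utils::write.table(d, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  names(d) <- sub("_.*$", "", names(d))
  sweep_set(d)
}
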