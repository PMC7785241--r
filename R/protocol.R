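#' Stimulation protocol
#'
#' Describes the input delivered to a single simulated neuron: an ordered
#' set of step-current segments, optional Poisson synaptic input, and an
#' optional piecewise-linear schedule for the energetic-health parameter
#' `alpha(t)` (used to emulate an accelerated disease progression within
#' one run).
#'
#' @param duration total simulated time (ms).
#' @param segments `NULL` or a data frame with columns `start`, `stop`
#'   (ms, within `[0, duration]`) and `amplitude` (pA). Overlapping
#'   segments sum.
#' @param poisson `NULL` or a list with fields `rate` (Hz, `>= 0`),
#'   `weight` (pA for exponential synapses, pA.ms charge for delta
#'   synapses), `kind` (`"exponential"` or `"delta"`), and `tau_syn`
#'   (ms, exponential kind only; default 2).
#' @param alpha_schedule `NULL` or a data frame with columns `time` (ms,
#'   increasing) and `alpha` (in `(0, 1]`); `alpha(t)` is interpolated
#'   linearly and held constant beyond the last knot.
#' @return an object of class `protocol`.
#' @examples
#' proto <- protocol(1000, segments = data.frame(start = 200, stop = 700,
#'                                               amplitude = 60))
#' @export
protocol <- function(duration, segments = NULL, poisson = NULL,
                     alpha_schedule = NULL) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    need <- c("start", "stop", "amplitude")
    if (!all(need %in% names(segments)))
      stop("segments needs columns start, stop, amplitude", call. = FALSE)
    segments <- segments[need]
    with(segments, {
      if (any(start < 0 | stop > duration | start >= stop))
        stop("segments must lie within [0, duration] with start < stop",
             call. = FALSE)
    })
  }
  if (!is.null(poisson)) {
    poisson <- utils::modifyList(
      list(rate = 0, weight = 0, kind = "exponential", tau_syn = 2),
      poisson)
    stopifnot(poisson$rate >= 0, poisson$tau_syn > 0)
    poisson$kind <- match.arg(poisson$kind, c("exponential", "delta"))
  }
  if (!is.null(alpha_schedule)) {
    alpha_schedule <- as.data.frame(alpha_schedule)
    if (!all(c("time", "alpha") %in% names(alpha_schedule)))
      stop("alpha_schedule needs columns time, alpha", call. = FALSE)
    if (is.unsorted(alpha_schedule$time))
      stop("alpha_schedule times must be increasing", call. = FALSE)
    if (any(alpha_schedule$alpha <= 0 | alpha_schedule$alpha > 1))
      stop("alpha_schedule values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(duration = duration, segments = segments,
                 poisson = poisson, alpha_schedule = alpha_schedule),
            class = "protocol")
}

#' Deterministic protocol current at given times
#'
#' Sum of all active step segments (Poisson input excluded).
#'
#' @param proto a [protocol()].
#' @param t numeric vector of times (ms).
#' @return current in pA, same length as `t`.
#' @export
protocol_current <- function(proto, t) {
  out <- numeric(length(t))
  seg <- proto$segments
  if (!is.null(seg))
    for (i in seq_len(nrow(seg)))
      out <- out + ifelse(t >= seg$start[i] & t < seg$stop[i],
                          seg$amplitude[i], 0)
  out
}

#' Single-step protocol helper
#'
#' A baseline - step - baseline protocol, the canonical input for behavior
#' classification.
#'
#' @param amplitude step amplitude (pA; negative = hyperpolarizing).
#' @param onset,offset step window (ms).
#' @param duration total duration (ms); default leaves a post-step tail for
#'   rebound detection.
#' @param ... passed to [protocol()].
#' @return a [protocol()].
#' @export
step_protocol <- function(amplitude, onset = 200, offset = onset + 500,
                          duration = offset + 500, ...) {
  protocol(duration,
           segments = data.frame(start = onset, stop = offset,
                                 amplitude = amplitude), ...)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %g ms", x$duration))
  if (!is.null(x$segments))
    cat(sprintf(", %d segment(s)", nrow(x$segments)))
  if (!is.null(x$poisson))
    cat(sprintf(", Poisson %g Hz (%s)", x$poisson$rate, x$poisson$kind))
  if (!is.null(x$alpha_schedule)) cat(", alpha schedule")
  cat("\n")
  invisible(x)
}
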