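#' Parameters of the energy-dependent leaky integrate-and-fire (eLIF) neuron
#'
#' The eLIF model couples a leaky integrate-and-fire membrane equation to an
#' energy variable `eps` (a phenomenological proxy for the ATP/ADP ratio).
#' Energy production relaxes `eps` towards `alpha * eps0`; consumption grows
#' as a cubic function of the membrane potential (Na/K-pump load), and each
#' spike costs `delta`. The leak potential is energy-dependent: it equals
#' `E0` at `eps = eps0` and rises to `Eu` when energy is depleted
#' (for `Eu > E0`), capturing the depolarization that follows pump failure.
#' A spike is emitted when `V >= Vth` *and* `eps >= epsc`; a depleted neuron
#' can sit above threshold without firing (depolarization block).
#'
#' @param Cm membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param E0 leak potential at `eps = eps0` (mV).
#' @param Eu leak potential at zero energy (mV). `Eu > E0` gives the
#'   integrator regime in which energy depletion depolarizes the neuron;
#'   `Eu < E0` gives a resonator-like regime.
#' @param Ef flex potential: inflection point of the energy nullcline (mV).
#' @param Ed energy-depletion potential: the lowest clamped potential that
#'   fully depletes the energy pool, and the point where the energy nullcline
#'   crosses `eps = 0` (mV).
#' @param Vth spike threshold (mV).
#' @param Vr post-spike reset potential (mV); must satisfy `Vr < Vth` for
#'   eLIF (hard threshold). For mAdExp only `Vr < Vpeak` is required:
#'   resetting above the soft threshold `Vth` is the classical
#'   burst-generating regime of adaptive exponential models.
#' @param eps0 reference energy scale (dimensionless energy units; presets
#'   normalise `eps0 = 1`).
#' @param epsc critical energy for spike emission (energy units, `>= 0`).
#' @param alpha energetic health in `(0, 1]`; `1` is a healthy neuron,
#'   values towards `0` model metabolic disease progression.
#' @param tau_e energy relaxation timescale (ms).
#' @param delta per-spike energy cost (energy units, `>= 0`).
#' @param Ie_baseline constant applied current added to every protocol (pA).
#'
#' @return An object of class `c("elif_params", "neuron_params")`: a named
#'   list of the parameters above. The derived membrane timescale is
#'   available through [tau_m()].
#' @seealso [madexp_params()], [neuron_state()], [simulate_neuron()],
#'   [find_fixed_points()]
#' @examples
#' p <- elif_params()
#' tau_m(p)
#' @export
elif_params <- function(Cm = 200, gL = 10, E0 = -65, Eu = -65, Ef = -60,
                        Ed = -30, Vth = -50, Vr = -65, eps0 = 1, epsc = 0.1,
                        alpha = 1, tau_e = 300, delta = 0.02,
                        Ie_baseline = 0) {
  p <- list(Cm = Cm, gL = gL, E0 = E0, Eu = Eu, Ef = Ef, Ed = Ed, Vth = Vth,
            Vr = Vr, eps0 = eps0, epsc = epsc, alpha = alpha, tau_e = tau_e,
            delta = delta, Ie_baseline = Ie_baseline)
  class(p) <- c("elif_params", "neuron_params")
  validate_params(p)
  p
}

#' Parameters of the modified adaptive exponential (mAdExp) neuron
#'
#' The mAdExp model extends [elif_params()] with the AdExp spike-initiation
#' and adaptation machinery. The exponential spike-initiation term is scaled
#' by `(eps - epsc)/eps0`, so energy depletion suppresses spike generation
#' without a hard threshold; the adaptation current `w` consumes energy at
#' rate `w/gamma` and receives an ATP-sensitive potassium (K-ATP) input
#' `epsc/(epsc + 2 eps) * I_KATP` that grows as energy falls.
#'
#' @inheritParams elif_params
#' @param DeltaT spike slope factor (mV, `> 0`).
#' @param Vpeak numerical spike cutoff (mV, `> Vth`): crossing it triggers
#'   the reset.
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA, `>= 0`).
#' @param tau_w adaptation timescale (ms, `> 0`).
#' @param gamma adaptation-to-energy conversion (pA per unit of energy
#'   consumption rate): `1/gamma` is the energetic cost per pA of adaptation
#'   current.
#' @param I_KATP maximal K-ATP current, reached at zero energy (pA, `>= 0`).
#'
#' @return An object of class
#'   `c("madexp_params", "elif_params", "neuron_params")`.
#' @examples
#' p <- madexp_params(a = 2, b = 40, tau_w = 200)
#' @export
madexp_params <- function(Cm = 200, gL = 10, E0 = -65, Eu = -65, Ef = -60,
                          Ed = -30, Vth = -50, Vr = -58, eps0 = 1,
                          epsc = 0.1, alpha = 1, tau_e = 300, delta = 0.02,
                          Ie_baseline = 0, DeltaT = 2, Vpeak = 0, a = 0,
                          b = 0, tau_w = 200, gamma = 200, I_KATP = 0) {
  p <- list(Cm = Cm, gL = gL, E0 = E0, Eu = Eu, Ef = Ef, Ed = Ed, Vth = Vth,
            Vr = Vr, eps0 = eps0, epsc = epsc, alpha = alpha, tau_e = tau_e,
            delta = delta, Ie_baseline = Ie_baseline, DeltaT = DeltaT,
            Vpeak = Vpeak, a = a, b = b, tau_w = tau_w, gamma = gamma,
            I_KATP = I_KATP)
  class(p) <- c("madexp_params", "elif_params", "neuron_params")
  validate_params(p)
  p
}

#' @export
is_madexp <- function(p) inherits(p, "madexp_params")

validate_params <- function(p) {
  stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
  num1 <- function(f) {
    v <- p[[f]]
    stop_if(!is.numeric(v) || length(v) != 1L || !is.finite(v),
            sprintf("parameter '%s' must be a single finite number", f))
  }
  for (f in names(p)) num1(f)
  stop_if(p$Cm <= 0, "invariant violated: Cm > 0")
  stop_if(p$gL <= 0, "invariant violated: gL > 0")
  stop_if(p$tau_e <= 0, "invariant violated: tau_e > 0")
  stop_if(p$eps0 <= 0, "invariant violated: eps0 > 0")
  stop_if(p$alpha <= 0 || p$alpha > 1, "invariant violated: alpha in (0, 1]")
  stop_if(p$delta < 0, "invariant violated: delta >= 0")
  stop_if(p$epsc < 0, "invariant violated: epsc >= 0")
  stop_if(p$Ed == p$Ef,
          "invariant violated: Ed != Ef (energy nullcline would degenerate)")
  # The hard-threshold eLIF needs Vr strictly below Vth (a reset at or above
  # threshold would re-fire instantly); in mAdExp Vth is only the soft
  # exponential threshold and resetting above it is the classical
  # burst-generating regime, so there the reset must only stay below the
  # spike-detection ceiling Vpeak.
  if (!is_madexp(p))
    stop_if(p$Vr >= p$Vth, "invariant violated: Vr < Vth")
  if (p$Ed < p$Ef)
    warning("Ed < Ef: energy consumption decreases with depolarization; ",
            "default presets use Ed > Ef", call. = FALSE)
  if (is_madexp(p)) {
    stop_if(p$Vr >= p$Vpeak, "invariant violated: Vr < Vpeak")
    stop_if(p$DeltaT <= 0, "invariant violated: DeltaT > 0")
    stop_if(p$tau_w <= 0, "invariant violated: tau_w > 0")
    stop_if(p$gamma <= 0, "invariant violated: gamma > 0")
    stop_if(p$Vpeak <= p$Vth, "invariant violated: Vpeak > Vth")
    stop_if(p$b < 0, "invariant violated: b >= 0")
    stop_if(p$I_KATP < 0, "invariant violated: I_KATP >= 0")
  }
  invisible(p)
}

#' Membrane timescale
#'
#' Derived quantity `tau_m = Cm / gL` (ms).
#'
#' @param p a [elif_params()] or [madexp_params()] object.
#' @return membrane time constant in ms.
#' @export
tau_m <- function(p) p$Cm / p$gL

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p a `neuron_params` object.
#' @param ... named scalar replacements, e.g. `alpha = 0.5`.
#' @return a validated `neuron_params` object of the same class.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(repl)] <- repl
  validate_params(p)
  p
}

#' Instantaneous state of a model neuron
#'
#' @param V membrane potential (mV).
#' @param eps available energy (energy units). May transiently cross below
#'   `epsc`; reaching `eps <= 0` while `V >= Ed` marks death.
#' @param w adaptation current (pA); held at 0 for eLIF neurons so both
#'   models share one state type.
#' @param alive viability flag; a dead state is frozen.
#' @return an object of class `neuron_state`.
#' @export
neuron_state <- function(V, eps, w = 0, alive = TRUE) {
  stopifnot(is.numeric(V), is.numeric(eps), is.numeric(w),
            length(V) == 1L, length(eps) == 1L, length(w) == 1L,
            is.logical(alive), length(alive) == 1L)
  structure(list(V = V, eps = eps, w = w, alive = alive),
            class = "neuron_state")
}

#' Resting state for a parameter set
#'
#' A convenient initial condition: energy at the sustainable level
#' `alpha * eps0`, membrane at the corresponding leak potential, zero
#' adaptation.
#'
#' @param p a `neuron_params` object.
#' @return a [neuron_state()].
#' @export
resting_state <- function(p) {
  eps <- p$alpha * p$eps0
  neuron_state(V = effective_leak(eps, p), eps = eps, w = 0)
}

#' @export
print.neuron_params <- function(x, ...) {
  kind <- if (is_madexp(x)) "mAdExp" else "eLIF"
  cat(sprintf("<%s parameters>  tau_m = %.3g ms\n", kind, tau_m(x)))
  flat <- unlist(x)
  out <- paste(sprintf("%s = %g", names(flat), flat), collapse = ", ")
  cat(strwrap(out, width = 76, indent = 2, exdent = 2), sep = "\n")
  invisible(x)
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("<neuron state> V = %.4g mV, eps = %.4g, w = %.4g pA%s\n",
              x$V, x$eps, x$w, if (x$alive) "" else " [dead]"))
  invisible(x)
}
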