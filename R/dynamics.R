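#' Energy-dependent leak potential
#'
#' The steady-state leak potential varies linearly with the energy level:
#' it equals `Eu` at zero energy and crosses `E0` at `eps = eps0`. For
#' `Eu > E0` this means that energy depletion depolarizes the neuron, the
#' phenomenological signature of a failing Na/K pump.
#'
#' @param eps energy level(s); any real value (the map is affine).
#' @param p an [elif_params()] or [madexp_params()] object.
#' @return leak potential(s) in mV: `E0 + (Eu - E0) * (1 - eps/eps0)`.
#' @examples
#' p <- elif_params(E0 = -65, Eu = -50)
#' effective_leak(p$eps0, p)  # E0
#' effective_leak(0, p)       # Eu
#' @export
effective_leak <- function(eps, p) {
  p$E0 + (p$Eu - p$E0) * (1 - eps / p$eps0)
}

#' ATP-sensitive potassium current
#'
#' Models K-ATP channels that open as the ATP/ADP ratio falls:
#' `I = epsc/(epsc + 2 eps) * I_KATP`, strictly decreasing in `eps`, equal
#' to the maximal current `I_KATP` at zero energy. When `epsc = 0` the term
#' is identically zero (the channel never activates); this is returned, not
#' raised, as the degenerate limit.
#'
#' @param eps energy level(s), `>= 0`.
#' @param p a [madexp_params()] object.
#' @return K-ATP current(s) in pA.
#' @export
katp_current <- function(eps, p) {
  if (p$epsc <= 0) return(rep(0, length(eps)))
  p$epsc / (p$epsc + 2 * eps) * p$I_KATP
}

check_state_finite <- function(s) {
  if (!all(is.finite(c(s$V, s$eps, s$w))))
    stop("invalid state: non-finite component", call. = FALSE)
  invisible(s)
}

#' Right-hand side of the eLIF flow
#'
#' Time derivatives of the smooth (between-spike) eLIF dynamics:
#' \deqn{C_m \dot V = g_L (E_L(\epsilon) - V) + I_{syn} + I_e}
#' \deqn{\tau_e \dot\epsilon = (1 - \epsilon/(\alpha\epsilon_0))^3 -
#'       (V - E_f)/(E_d - E_f)}
#' The production term relaxes energy towards the sustainable level
#' `alpha * eps0`; the cubic consumption term grows with depolarization and
#' vanishes at the flex potential `Ef`.
#'
#' @param s a [neuron_state()] with `alive = TRUE`.
#' @param p an [elif_params()] object.
#' @param I_syn synaptic current (pA).
#' @param I_e applied current (pA); defaults to the parameter set's baseline.
#' @return named numeric vector `c(dV, deps)` in mV/ms and energy-units/ms.
#' @export
elif_rhs <- function(s, p, I_syn = 0, I_e = p$Ie_baseline) {
  stopifnot(s$alive)
  check_state_finite(s)
  EL <- effective_leak(s$eps, p)
  dV <- (p$gL * (EL - s$V) + I_syn + I_e) / p$Cm
  deps <- ((1 - s$eps / (p$alpha * p$eps0))^3 -
           (s$V - p$Ef) / (p$Ed - p$Ef)) / p$tau_e
  c(dV = dV, deps = deps)
}

#' Right-hand side of the mAdExp flow
#'
#' Time derivatives of the smooth mAdExp dynamics (valid for `V < Vpeak`).
#' Relative to the eLIF flow, the voltage equation gains the
#' energy-gated exponential spike-initiation term
#' `gL * DeltaT * (eps - epsc)/eps0 * exp((V - Vth)/DeltaT)` and the
#' adaptation current `-w`; the energy equation gains the adaptation cost
#' `-w/gamma`; and `w` relaxes with timescale `tau_w` towards
#' `a (V - EL) + I_KATP * epsc/(epsc + 2 eps)`. The exponent is clamped at
#' +20 before exponentiation to guard against overflow (the trajectory is
#' cut at `Vpeak` in any case). In the energy and adaptation equations the
#' voltage is capped at `Vpeak`: above the spike-detection ceiling the
#' trajectory is "in spike", whose energetic and adaptation costs are the
#' discrete reset increments `delta` and `b`, not the (solver-dependent)
#' suprathreshold overshoot.
#'
#' @inheritParams elif_rhs
#' @param p a [madexp_params()] object.
#' @return named numeric vector `c(dV, deps, dw)`.
#' @export
madexp_rhs <- function(s, p, I_syn = 0, I_e = p$Ie_baseline) {
  stopifnot(s$alive)
  check_state_finite(s)
  EL <- effective_leak(s$eps, p)
  ex <- pmin((s$V - p$Vth) / p$DeltaT, 20)
  Vc <- min(s$V, p$Vpeak)
  dV <- (p$gL * (EL - s$V) +
         p$gL * p$DeltaT * (s$eps - p$epsc) / p$eps0 * exp(ex) -
         s$w + I_syn + I_e) / p$Cm
  deps <- ((1 - s$eps / (p$alpha * p$eps0))^3 -
           (Vc - p$Ef) / (p$Ed - p$Ef) - s$w / p$gamma) / p$tau_e
  dw <- (p$a * (Vc - EL) - s$w + katp_current(s$eps, p)) / p$tau_w
  c(dV = dV, deps = deps, dw = dw)
}

#' Spike condition
#'
#' eLIF: fires iff `V >= Vth` *and* `eps >= epsc` (a superthreshold neuron
#' with depleted energy does not spike — depolarization block). Ties at
#' `eps = epsc` count as spiking. mAdExp: fires iff `V >= Vpeak`; energy
#' gating acts implicitly through the suppressed exponential.
#'
#' @param s a [neuron_state()].
#' @param p a `neuron_params` object.
#' @return logical.
#' @export
spike_condition <- function(s, p) {
  if (is_madexp(p)) s$V >= p$Vpeak else (s$V >= p$Vth && s$eps >= p$epsc)
}

#' Post-spike reset
#'
#' Applies the discontinuous part of the hybrid dynamics: `V <- Vr`,
#' `eps <- eps - delta`, and for mAdExp additionally `w <- w + b`. Energy
#' may go negative transiently; viability is judged by the integrator,
#' not here.
#'
#' @param s a [neuron_state()] satisfying [spike_condition()].
#' @param p a `neuron_params` object.
#' @return the reset [neuron_state()].
#' @export
apply_reset <- function(s, p) {
  s$V <- p$Vr
  s$eps <- s$eps - p$delta
  if (is_madexp(p)) s$w <- s$w + p$b
  s
}
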