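#' V-nullcline of the eLIF system
#'
#' Potential at which `dV/dt = 0` for a given energy level:
#' `effective_leak(eps) + I_total/gL`. An applied current shifts the line
#' by `I/gL`, towards more negative potentials when `I < 0`.
#'
#' @param eps energy level(s).
#' @param p an [elif_params()] object.
#' @param I_total total constant input current (pA).
#' @return potential(s) in mV.
#' @export
v_nullcline <- function(eps, p, I_total = 0) {
  effective_leak(eps, p) + I_total / p$gL
}

#' Energy nullcline of the eLIF system
#'
#' Potential at which `deps/dt = 0` for a given energy level:
#' `Ef + (Ed - Ef) * (1 - eps/(alpha eps0))^3`, a cubic with inflection at
#' `eps = alpha * eps0` (where it crosses the flex potential `Ef`) that
#' meets `eps = 0` at the depletion potential `Ed`.
#'
#' @inheritParams v_nullcline
#' @return potential(s) in mV.
#' @export
eps_nullcline <- function(eps, p) {
  p$Ef + (p$Ed - p$Ef) * (1 - eps / (p$alpha * p$eps0))^3
}

elif_jacobian <- function(p, eps) {
  matrix(c(-p$gL / p$Cm,
           -1 / ((p$Ed - p$Ef) * p$tau_e),
           -p$gL * (p$Eu - p$E0) / (p$eps0 * p$Cm),
           -3 * (1 - eps / (p$alpha * p$eps0))^2 / (p$alpha * p$eps0 *
                                                    p$tau_e)),
         nrow = 2)
}

stability_label <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  marginal <- any(abs(re) <= tol)
  lab <- if (marginal) "unstable"
         else if (all(re < 0)) "stable"
         else if (any(re < 0) && any(re > 0) && all(Im(ev) == 0)) "saddle"
         else "unstable"
  list(label = lab, marginal = marginal)
}

#' Fixed points of a model neuron under constant input
#'
#' eLIF: all roots of `v_nullcline(eps) - eps_nullcline(eps)` inside the
#' energy search window (default `[0, 2 eps0]`), located by a dense sign
#' scan and refined by bracketed bisection ([stats::uniroot()]); stability
#' from the eigenvalues of the analytic 2x2 Jacobian. mAdExp: roots of the
#' full 3-D system located by damped Newton iteration from multiple seeds
#' (the eLIF fixed points plus a grid), with a numerical 3x3 Jacobian.
#' Fixed points with `eps < 0` are discarded as biophysically unacceptable.
#' An empty result maps to the "nonviable" regime (no sustainable state).
#'
#' @param p an [elif_params()] or [madexp_params()] object.
#' @param I_total constant input current (pA).
#' @param eps_window numeric length-2 search window for the energy level.
#' @param n_grid number of scan points.
#' @return data frame with one row per fixed point (ordered by `eps`):
#'   columns `V`, `eps`, `w`, `stability` (`"stable"`, `"unstable"`,
#'   `"saddle"`), `marginal` (near-zero eigenvalue real part) and
#'   `in_continuous_region` (`V < Vth` or `eps < epsc`, the eLIF
#'   quiescence criterion).
#' @examples
#' p <- load_preset("fig3_bistable")$model
#' find_fixed_points(p)  # 3 fixed points: stable / saddle / stable
#' @export
find_fixed_points <- function(p, I_total = 0,
                              eps_window = c(0, 2 * p$eps0),
                              n_grid = 4001) {
  if (is_madexp(p))
    return(find_fixed_points_madexp(p, I_total, eps_window, n_grid))
  f <- function(e) v_nullcline(e, p, I_total) - eps_nullcline(e, p)
  grid <- seq(eps_window[1], eps_window[2], length.out = n_grid)
  fg <- f(grid)
  roots <- grid[fg == 0]
  sw <- which(fg[-1] * fg[-n_grid] < 0)
  for (i in sw)
    roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                     tol = 1e-13)$root)
  roots <- sort(unique(roots))
  roots <- roots[roots >= 0]
  rows <- lapply(roots, function(e) {
    st <- stability_label(eigen(elif_jacobian(p, e),
                                only.values = TRUE)$values)
    V <- v_nullcline(e, p, I_total)
    data.frame(V = V, eps = e, w = 0, stability = st$label,
               marginal = st$marginal,
               in_continuous_region = (V < p$Vth) || (e < p$epsc))
  })
  if (!length(rows))
    return(data.frame(V = numeric(), eps = numeric(), w = numeric(),
                      stability = character(), marginal = logical(),
                      in_continuous_region = logical()))
  do.call(rbind, rows)
}

madexp_flow <- function(x, p, I_total) {
  s <- neuron_state(x[1], x[2], x[3])
  unname(madexp_rhs(s, p, I_syn = 0, I_e = I_total))
}

num_jacobian <- function(fn, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- fn(x)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    J[, j] <- (fn(xp) - f0) / hj
  }
  J
}

newton_root <- function(fn, x0, maxit = 100, tol = 1e-11) {
  x <- x0
  for (it in seq_len(maxit)) {
    f0 <- fn(x)
    if (!all(is.finite(f0))) return(NULL)
    if (max(abs(f0)) < tol) return(x)
    J <- num_jacobian(fn, x)
    step <- tryCatch(solve(J, f0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lam <- 1
    repeat {  # damping: accept only residual-reducing steps
      xn <- x - lam * step
      fn1 <- fn(xn)
      if (all(is.finite(fn1)) && max(abs(fn1)) < max(abs(f0))) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn
  }
  if (max(abs(fn(x))) < 1e-8) x else NULL
}

find_fixed_points_madexp <- function(p, I_total, eps_window, n_grid) {
  # scale the flow so the Newton tolerance is comparable across components
  fl <- function(x) madexp_flow(x, p, I_total) * c(1, 1e3, 10)
  seeds <- list()
  elif_fp <- find_fixed_points(as_elif(p), I_total, eps_window,
                               min(n_grid, 2001))
  for (i in seq_len(nrow(elif_fp))) {
    e <- elif_fp$eps[i]; V <- elif_fp$V[i]
    w <- p$a * (V - effective_leak(e, p)) + katp_current(e, p)
    seeds[[length(seeds) + 1]] <- c(V, e, w)
  }
  eg <- seq(max(eps_window[1], 1e-3), eps_window[2], length.out = 9)
  vg <- seq(min(p$E0, p$Eu) - 20, p$Vth + 2 * p$DeltaT, length.out = 7)
  for (e in eg) for (V in vg) {
    w <- p$a * (V - effective_leak(e, p)) + katp_current(e, p)
    seeds[[length(seeds) + 1]] <- c(V, e, w)
  }
  roots <- list()
  for (s in seeds) {
    r <- newton_root(fl, s)
    if (is.null(r)) next
    if (r[2] < 0 || r[2] < eps_window[1] - 1e-9 ||
        r[2] > eps_window[2] + 1e-9) next
    dup <- any(vapply(roots, function(q)
      abs(q[1] - r[1]) < 1e-5 && abs(q[2] - r[2]) < 1e-7, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (!length(roots))
    return(data.frame(V = numeric(), eps = numeric(), w = numeric(),
                      stability = character(), marginal = logical(),
                      in_continuous_region = logical()))
  roots <- roots[order(vapply(roots, `[`, numeric(1), 2))]
  rows <- lapply(roots, function(r) {
    J <- num_jacobian(function(x) madexp_flow(x, p, I_total), r)
    st <- stability_label(eigen(J, only.values = TRUE)$values)
    data.frame(V = r[1], eps = r[2], w = r[3], stability = st$label,
               marginal = st$marginal,
               in_continuous_region = (r[1] < p$Vth) || (r[2] < p$epsc))
  })
  do.call(rbind, rows)
}

#' Phase portrait of the eLIF system
#'
#' Samples both nullclines over an energy window and attaches the fixed
#' points, for plotting and inspection.
#'
#' @inheritParams find_fixed_points
#' @param n number of nullcline samples.
#' @return object of class `phase_portrait`: list with `eps` (sample grid),
#'   `v_null`, `eps_null` (mV), `fixed_points` (as [find_fixed_points()]),
#'   `I_total` and `params`.
#' @export
phase_portrait <- function(p, I_total = 0, eps_window = c(0, 2 * p$eps0),
                           n = 400) {
  eps <- seq(eps_window[1], eps_window[2], length.out = n)
  structure(list(eps = eps,
                 v_null = v_nullcline(eps, as_elif(p), I_total),
                 eps_null = eps_nullcline(eps, as_elif(p)),
                 fixed_points = find_fixed_points(p, I_total, eps_window),
                 I_total = I_total, params = p),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase portrait> I = %g pA, %d fixed point(s)\n",
              x$I_total, nrow(x$fixed_points)))
  if (nrow(x$fixed_points)) print(x$fixed_points)
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  plot(x$eps, x$v_null, type = "l", col = "blue", xlab = "energy",
       ylab = "V (mV)",
       ylim = range(c(x$v_null, x$eps_null, x$fixed_points$V)), ...)
  graphics::lines(x$eps, x$eps_null, col = "red")
  if (nrow(x$fixed_points))
    graphics::points(x$fixed_points$eps, x$fixed_points$V,
                     pch = ifelse(x$fixed_points$stability == "stable",
                                  19, 1))
  invisible(x)
}

#' Saddle-node bifurcation currents of the eLIF neuron
#'
#' The two applied currents at which a stable and an unstable fixed point
#' merge, bounding the bistable (three-fixed-point) interval. Computed
#' numerically from the tangency condition: the energy-derivative of the
#' nullcline difference is independent of the current, so its roots give
#' the tangency energies, and the current follows from equating the
#' nullclines there. The algebraic closed form
#' `I = gL * (Ef - Eu + alpha (Eu - E0) * (1 -/+ (2/3) sqrt(alpha (Eu - E0)
#' / (3 (Ed - Ef)))))` is attached as attribute `"closed_form"` for
#' cross-checking; the numerical tangency solution is the authoritative
#' output.
#'
#' When no real tangency exists (e.g. `Eu = E0`, where the bistable
#' interval collapses) both returned values equal
#' `gL (Ef - Eu + alpha (Eu - E0))` and the `degenerate` attribute is set.
#'
#' @param p an [elif_params()] object with `Eu > E0` for a genuine
#'   bistable-capable regime.
#' @param eps_window energy window searched for tangencies.
#' @return named numeric vector `c(I_minus, I_plus)` (pA), with attributes
#'   `degenerate` (logical), `eps_tangency`, and `closed_form`.
#' @export
saddle_node_currents <- function(p, eps_window = c(0, 2 * p$eps0)) {
  stopifnot(!is_madexp(p) || !is.null(p$eps0))
  K <- p$alpha * (p$Eu - p$E0) / (3 * (p$Ed - p$Ef))
  cf <- p$gL * (p$Ef - p$Eu + p$alpha * (p$Eu - p$E0) *
                (1 + c(-2, 2) / 3 * sqrt(max(K, 0))))
  dnull <- function(e)  # d/deps [v_nullcline - eps_nullcline]
    -(p$Eu - p$E0) / p$eps0 +
      3 * (p$Ed - p$Ef) * (1 - e / (p$alpha * p$eps0))^2 /
        (p$alpha * p$eps0)
  grid <- seq(eps_window[1], eps_window[2], length.out = 2001)
  dg <- dnull(grid)
  sw <- which(dg[-1] * dg[-length(dg)] < 0)
  tang <- vapply(sw, function(i)
    stats::uniroot(dnull, c(grid[i], grid[i + 1]), tol = 1e-13)$root,
    numeric(1))
  tang <- c(tang, grid[dg == 0])
  if (length(tang) < 2 || K <= 0) {
    I <- p$gL * (p$Ef - p$Eu + p$alpha * (p$Eu - p$E0))
    out <- c(I_minus = I, I_plus = I)
    attr(out, "degenerate") <- TRUE
    attr(out, "eps_tangency") <- rep(p$alpha * p$eps0, 2)
    attr(out, "closed_form") <- c(I_minus = I, I_plus = I)
    return(out)
  }
  tang <- sort(tang)[c(1, length(tang))]
  I <- p$gL * (eps_nullcline(tang, p) - effective_leak(tang, p))
  out <- sort(I)
  names(out) <- c("I_minus", "I_plus")
  attr(out, "degenerate") <- FALSE
  attr(out, "eps_tangency") <- tang
  attr(out, "closed_form") <- c(I_minus = min(cf), I_plus = max(cf))
  out
}

#' Rebound-spiking threshold of the mAdExp neuron
#'
#' For `Eu > E0` the energy-raised leak can make the V-nullcline diverge
#' upwards before the threshold, creating a stable fixed point between
#' `V* = Vth + DeltaT * log((Eu - E0)/DeltaT)` and `Vth`. The rebound
#' bifurcation regime requires `Eu - E0 < DeltaT` (then `V* < Vth`): a
#' hyperpolarized, energy-replete neuron released from inhibition can
#' overshoot and fire without any sag.
#'
#' @param p a [madexp_params()] object.
#' @return list with `V_star` (mV, `NA` if `Eu <= E0`) and `applicable`
#'   (`TRUE` iff `0 < Eu - E0 < DeltaT`).
#' @export
rebound_threshold <- function(p) {
  stopifnot(is_madexp(p))
  d <- p$Eu - p$E0
  if (d <= 0) return(list(V_star = NA_real_, applicable = FALSE))
  list(V_star = p$Vth + p$DeltaT * log(d / p$DeltaT),
       applicable = d < p$DeltaT)
}

#' Classify the dynamical regime under constant input
#'
#' Derived from [find_fixed_points()]: three fixed points give a bistable
#' cell; a single fixed point is a normal resting state if subthreshold,
#' a tonically spiking state if superthreshold with enough energy, or an
#' energy-blocked (depolarized, unresponsive) state if its energy lies at
#' or below `epsc`; no fixed point is unsustainable and leads to neuronal
#' death.
#'
#' @inheritParams find_fixed_points
#' @return one of `"single-rest"`, `"bistable"`, `"tonic-spiking"`,
#'   `"energy-blocked"`, `"nonviable"`.
#' @export
classify_regime <- function(p, I_total = 0,
                            eps_window = c(0, 2 * p$eps0)) {
  fp <- find_fixed_points(p, I_total, eps_window)
  n <- nrow(fp)
  if (n == 0) return("nonviable")
  if (n >= 2) return("bistable")
  if (fp$eps <= p$epsc) return("energy-blocked")
  if (fp$V < p$Vth) return("single-rest")
  "tonic-spiking"
}

#' Sweep the energetic-health parameter
#'
#' Re-evaluates fixed points and regime over a descending grid of `alpha`
#' values, tracking the disease progression from a healthy resting neuron
#' through bistability and hyperexcitability to the energy-blocked state.
#'
#' @param p an [elif_params()] object (the `alpha` field is overridden).
#' @param alpha_grid values in `(0, 1]`, typically descending.
#' @param I_total constant input current (pA).
#' @return object of class `alpha_sweep`: list with `table` (data frame:
#'   `alpha`, `n_fixed_points`, `regime`), `fixed_points` (list of per-alpha
#'   data frames) and `stages` (the compressed regime sequence, consecutive
#'   duplicates merged).
#' @examples
#' p <- load_preset("fig4_disease")$model
#' sw <- alpha_sweep(p, seq(1, 0.3, by = -0.01))
#' sw$stages
#' @export
alpha_sweep <- function(p, alpha_grid, I_total = 0) {
  stopifnot(all(alpha_grid > 0 & alpha_grid <= 1))
  fps <- lapply(alpha_grid, function(a)
    find_fixed_points(update_params(p, alpha = a), I_total))
  regime <- vapply(alpha_grid, function(a)
    classify_regime(update_params(p, alpha = a), I_total), character(1))
  tab <- data.frame(alpha = alpha_grid,
                    n_fixed_points = vapply(fps, nrow, integer(1)),
                    regime = regime)
  structure(list(table = tab, fixed_points = fps,
                 stages = rle(regime)$values, I_total = I_total),
            class = "alpha_sweep")
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat(sprintf("<alpha sweep> %d levels, stages: %s\n", nrow(x$table),
              paste(x$stages, collapse = " -> ")))
  invisible(x)
}

#' Stationary frequency-current (I-f) curve
#'
#' Simulates the neuron under each constant current and reports the
#' steady-state firing rate, estimated from the spike count in the second
#' half of the run. The run should be long relative to the energy
#' timescale (`T >= 5 tau_e`) for the rate to be stationary.
#'
#' @param p a `neuron_params` object.
#' @param I_grid currents to probe (pA).
#' @param T run duration (ms); default `max(5 tau_e, 1000)`.
#' @param dt integration step (ms).
#' @return data frame with columns `I` (pA) and `rate` (Hz).
#' @export
if_curve <- function(p, I_grid, T = max(5 * p$tau_e, 1000), dt = 0.05) {
  rate <- vapply(I_grid, function(I) {
    r <- simulate_neuron(p, protocol(T, segments = data.frame(
      start = 0, stop = T, amplitude = I)), dt = dt)
    sum(r$spikes > T / 2) / (T / 2) * 1e3
  }, numeric(1))
  data.frame(I = I_grid, rate = rate)
}
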