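---
title: "metaneuron: energy-constrained neuron models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaneuron: energy-constrained neuron models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaneuron)
```

This vignette documents the methods implemented in **metaneuron**: the
model equations, the phase-plane machinery, the integrators, the behavior
classifier, the network simulation, and the subthreshold fitting
estimators. The models follow Fardet & Levina (2020), *PLOS Computational
Biology* 16(12): e1008503 (doi:10.1371/journal.pcbi.1008503); the shipped
presets are frozen parameter sets reproducing that article's figures.

## 1. Model equations

### eLIF

The energy-dependent LIF neuron couples the membrane potential $V$ to an
energy variable $\epsilon$ (a proxy for the ATP/ADP ratio):

$$
C_m \dot V = g_L\,(E_L(\epsilon) - V) + I, \qquad
\tau_\epsilon \dot\epsilon =
  \Big(1 - \frac{\epsilon}{\alpha\,\epsilon_0}\Big)^3
  - \frac{V - E_f}{E_d - E_f},
$$

with the energy-dependent leak potential

$$
E_L(\epsilon) = E_0 + (E_u - E_0)\Big(1 - \frac{\epsilon}{\epsilon_0}\Big).
$$

The cubic production term relaxes $\epsilon$ towards the health-dependent
target $\alpha\,\epsilon_0$ ($\alpha = 1$ healthy); the linear consumption
term grows with depolarization, vanishing at $E_f$ and reaching 1 at
$E_d$. A spike is emitted when **both** $V \ge V_{th}$ and
$\epsilon \ge \epsilon_c$; the reset map is $V \leftarrow V_r$,
$\epsilon \leftarrow \epsilon - \delta$. With $E_u = E_0$, $\delta = 0$
and $\epsilon_c = 0$ the model reduces exactly to the classical LIF
neuron (`elif_rhs()` and the test suite verify this against the
closed-form charging curve).

### mAdExp

The modified AdExp neuron adds the exponential spike-initiation term —
scaled by available energy — and an adaptation current $w$ that includes
an ATP-gated potassium (K-ATP) component:

$$
C_m \dot V = g_L (E_L(\epsilon) - V)
 + g_L \Delta_T \frac{\epsilon - \epsilon_c}{\epsilon_0}
   \exp\!\Big(\frac{V - V_{th}}{\Delta_T}\Big) - w + I,
$$
$$
\tau_w \dot w = a\,(V - E_L(\epsilon)) - w + I_{KATP}(\epsilon), \qquad
I_{KATP}(\epsilon) = \frac{I_{KATP}^{max}}{1 + \epsilon/\epsilon_c},
$$

with the energy equation as in the eLIF (consumption additionally scales
with $w$ through $\gamma$). Spikes are detected at $V \ge V_{peak}$ and
add $b$ to $w$. When the energy prefactor is pinned at 1 and K-ATP is
off, the model reduces exactly to AdExp; `tests/testthat` verifies the
trace against an adaptive-step `deSolve` reference to $10^{-6}$ mV.

Numerical safeguards: the exponential argument is clamped, and $V$ is
capped at $V_{peak}$ inside the $\epsilon$ and $w$ equations so the
energy drain during a spike upstroke stays bounded.

```{r rhs}
p <- elif_params()
elif_rhs(neuron_state(-60, 0.8), p, I_e = 30)
```

## 2. Phase-plane analysis

For the eLIF the $(\epsilon, V)$ plane has two nullclines:
`v_nullcline()` (where $\dot V = 0$; a line in $\epsilon$) and
`eps_nullcline()` (where $\dot\epsilon = 0$; a cubic). Their
intersections are found by a dense sign scan plus root polishing
(`find_fixed_points()`), and each fixed point is classified by the
Jacobian eigenvalues.

```{r phase}
p <- load_preset("fig3_bistable")$model
find_fixed_points(p)
```

Three fixed points — a depolarized "up" state, a saddle, and a
hyperpolarized "down" state — make the cell bistable: brief current
pulses switch it between states, the substrate of up/down dynamics and
of pathological locking into a depolarized state.

`saddle_node_currents()` returns the two input currents $I_\pm$ at which
the stable/saddle pairs collide (computed by a tangency solver and
cross-checked against a closed form); between them the cell is bistable.
At $E_u = E_0$ the interval collapses degenerately to
$g_L (E_f - E_0)$. `rebound_threshold()` implements the rebound
condition of the mAdExp model: when $0 < E_u - E_0 < \Delta_T$ there is
a potential
$V^* = V_{th} + \Delta_T \ln\!\big((E_u - E_0)/\Delta_T\big)$ such that
a rest state in $(V^*, V_{th})$ is destabilized by the extra energy
accumulated during hyperpolarization — producing rebound spikes with
**no sag**, unlike the classical adaptation-driven mechanism
(`rebound_mode()` separates the two).

### Disease progression

Declining metabolic health is modelled by lowering $\alpha$.
`alpha_sweep()` tracks the fixed-point structure across an $\alpha$ grid
and compresses it into qualitative stages:

```{r alpha}
sw <- alpha_sweep(load_preset("fig4_disease")$model, seq(1, 0.3, by = -0.01))
sw$stages
```

A healthy single rest state first becomes bistable (comorbid up-states),
then loses its rest state entirely (spontaneous tonic spiking —
hyperactivity), and finally becomes energy-blocked: depolarized above
threshold but unable to spike because $\epsilon < \epsilon_c$.

## 3. Simulation

`simulate_neuron()` integrates the hybrid system with a fixed-step
classical RK4 scheme (Euler available) implemented in C++. Protocols
(`protocol()`, `step_protocol()`) combine step segments, Poisson input
(exponential or delta synapses), and a piecewise-linear $\alpha$
schedule. Spikes are detected at the end of each step, so spike times
carry at most one step of bias; the test suite enforces a drift bound
under `dt` halving for every preset. Additional mechanics:

- **refractoriness** — an optional absolute refractory clamp at $V_r$;
- **depolarization block** — `detect_depolarization_block()` finds
  intervals where the neuron sits above its spiking range without
  emitting spikes;
- **cell death** — if the energy collapses at a high potential with no
  recovery possible, the state is frozen and `death_time` recorded;
- **determinism** — all stochastic inputs are seeded.

```{r simulate}
cfg <- load_preset("fig6_RB")
r <- simulate_neuron(cfg$model, cfg$protocol)
length(r$spikes)
```

## 4. Behavior classification

`extract_features()` computes first-spike latency, the ISI sequence and
adaptation index, a burstiness index (2-means split of the log-ISIs),
burst counts and inter-burst gap regularity, the sag ratio on
hyperpolarizing steps, rebound spike counts, and depolarization-block
intervals. `classify_behavior()` maps these onto the qualitative
repertoire — RS, AS (adapting), IB (initial burst), RB (regular
bursting), IS (intermittent), TS (transient), DB/DA (delayed), IR/ER
(rebound after inhibition/excitation), depol-block, silent — with
decision thresholds collected in `behavior_thresholds()`. Each
`fig6_*` preset, simulated at its shipped step current, reproduces its
nominal label, and every one of them enters depolarization block at the
higher reference current (`fig6_reference_currents()`):

```{r classify}
classify_behavior(r, thresholds = cfg$classifier)$label
head(fig6_reference_currents(), 4)
```

## 5. Networks

`network_spec()` / `build_network()` define a sparse random E/I network
(default: 1000 eLIF neurons, 80% excitatory, 10% connectivity, delayed
current-based exponential synapses, independent Poisson background).
`simulate_network()` is a compiled clock-driven simulation; a
homeostasis table maps each health level $\alpha$ to small
threshold/reset shifts that keep the background rate fixed, so that
network-level effects of energy constraints can be studied at constant
mean activity. `compute_network_stats()` yields per-neuron rates, ISI
CVs and the mean pairwise count correlation; the asynchronous-irregular
(AI) criterion requires mean CC below $1/N$ and mean CV in $[0.5, 1.2]$.

```{r network, eval = FALSE}
net <- build_network(network_spec())
res <- simulate_network(net, load_preset("fig5_network_neuron")$model,
                        alpha = 1, duration = 5500, seed = 1)
compute_network_stats(res, window = c(500, 5500))
#> <network stats> median rate 2 Hz, mean CV 0.809, mean CC 0.000515 (1/N = 0.001) [AI]
```

With the stimulus window enabled (`stimulus_on = TRUE`),
`stimulus_response_profile()` quantifies how a strongly driven subset
responds: healthy networks sustain elevated firing through the stimulus,
whereas energy-impaired ones fragment it, as energy depletion throttles
the response.

## 6. Subthreshold fitting

`sweep_set()` ingests current-clamp sweeps (`t`, `V`, `I`);
`estimate_EL()` takes the median of pooled baselines,
`estimate_tau_m()` fits the RC charging curve over the initial-slope
window of hyperpolarizing sweeps (a straight-line fit over a finite
window underestimates the onset slope by about $T/(2\tau_m)$, so the
exponential form is fitted instead), and `estimate_gL_plus_a()`
regresses steady-state deflections on current. `discrepancy()` provides
a weighted spike-and-trace objective for externally driven parameter
tuning. `make_fixtures()` generates deterministic synthetic sweeps and
spike trains with known ground truth:

```{r fitting}
fx <- make_fixtures(file.path(tempdir(), "fx"), seed = 1)
subthreshold_features(read_sweeps(fx$sweeps_elif))
```

## 7. Reproduction

`scripts/acceptance.R` (in the source tree) recomputes the four
headline targets — AI-network median rate $2 \pm 0.5$ Hz, mean ISI CV
$\ge 0.7$, 3 fixed points in the bistable preset, 4 disease-progression
stages — against the installed package and writes them as JSON. The
test suite in `tests/testthat/` contains one acceptance block per
target plus the property checks (closed-form limits, root-finding
oracle, saddle-node bracketing, rebound identities, sub-$1/N$
correlations, classifier self-consistency, fitting recovery,
integrator convergence).
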