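# metaneuron

Simulation and analysis of **energy-constrained integrate-and-fire neuron
models**: the energy-dependent leaky integrate-and-fire neuron (**eLIF**)
and the modified adaptive exponential integrate-and-fire neuron
(**mAdExp**), as introduced by Fardet & Levina (2020), *Simple models
including energy and spike constraints reproduce complex activity patterns
and metabolic disruptions*, PLOS Computational Biology 16(12): e1008503
(doi:[10.1371/journal.pcbi.1008503](https://doi.org/10.1371/journal.pcbi.1008503)).

## The models in one paragraph

Both models extend classical hybrid integrate-and-fire dynamics with an
explicit energy variable ϵ, a phenomenological proxy for the cellular
ATP/ADP ratio. Energy is produced towards a health-dependent target
α·ϵ₀ (α = 1 healthy, α < 1 metabolically impaired) and consumed by
depolarization; crucially, **a spike can only be emitted when ϵ ≥ ϵ_c**,
and each spike consumes a fixed amount δ. The energy level also feeds
back onto the membrane: the effective leak potential rises as energy
drops (Na/K-pump failure), and in the mAdExp model low energy both scales
down the exponential spike-initiation term and opens an ATP-gated
potassium current. These couplings reproduce — with only two or four
state variables — behaviors that standard LIF/AdExp neurons cannot:
depolarization block, energy-limited bursting, rebound spiking without a
sag, bistable up/down states, and the progressive stages of metabolic
disease, while remaining cheap enough for large network simulations.

## Worked example

Phase-plane analysis of the shipped bistable cell, a single-neuron
simulation, the four-stage disease progression, and the recurrent
network preset:

```r
library(metaneuron)

## 1. Bistability: the (V, eps) phase plane has two stable states
cfg <- load_preset("fig3_bistable")
find_fixed_points(cfg$model)
#>           V       eps w stability marginal in_continuous_region
#> 1 -58.09056 0.5393708 0    stable    FALSE                 TRUE
#> 2 -61.48552 0.7657012 0    saddle    FALSE                 TRUE
#> 3 -75.42392 1.6949280 0    stable    FALSE                 TRUE

## 2. Behavior classification of an mAdExp bursting preset
cfg <- load_preset("fig6_RB")
r <- simulate_neuron(cfg$model, cfg$protocol)
classify_behavior(r, thresholds = cfg$classifier)
#> <behavior> RB  (12 step spikes, adaptation 0.924, burstiness 0.126, rebound 0)

## 3. Disease progression: sweep the energetic-health parameter alpha
sw <- alpha_sweep(load_preset("fig4_disease")$model, seq(1, 0.3, by = -0.01))
sw$stages
#> [1] "single-rest"    "bistable"       "tonic-spiking"  "energy-blocked"

## 4. Asynchronous-irregular activity in a 1000-neuron E/I network
net <- build_network(network_spec())
res <- simulate_network(net, load_preset("fig5_network_neuron")$model,
                        alpha = 1, duration = 5500, seed = 1)
compute_network_stats(res, window = c(500, 5500))
#> <network stats> median rate 2 Hz, mean CV 0.809, mean CC 0.000515 (1/N = 0.001) [AI]
```

## Package tour

- **Core models** — `elif_params()`, `madexp_params()`, right-hand sides
  (`elif_rhs()`, `madexp_rhs()`), the spike condition and reset map, and
  degenerate limits that recover the classical LIF and AdExp models
  exactly.
- **Phase-plane analysis** — `v_nullcline()`, `eps_nullcline()`,
  `find_fixed_points()` (with stability), `saddle_node_currents()`,
  `rebound_threshold()`, `classify_regime()`, `alpha_sweep()`,
  `if_curve()`, `phase_portrait()`.
- **Simulation** — `simulate_neuron()`: fixed-step RK4 (or Euler)
  integration with step/Poisson protocols (`protocol()`,
  `step_protocol()`), time-varying health schedules, refractoriness,
  depolarization-block detection (`detect_depolarization_block()`) and
  cell-death handling.
- **Behavior classification** — `extract_features()` /
  `classify_behavior()` map step responses to the qualitative repertoire
  (RS, AS, IB, RB, TS, DB, DA, IR, ER, IS, depol-block, silent);
  `rebound_mode()` separates sag-mediated from energy-mediated rebound.
- **Networks** — `network_spec()`, `build_network()`,
  `simulate_network()` (compiled clock-driven E/I simulation with delayed
  current-based synapses and Poisson background),
  `compute_network_stats()` (rates, ISI CV, pairwise correlations, AI
  criterion) and `stimulus_response_profile()`.
- **Fitting** — `sweep_set()` plus estimators for the resting potential,
  membrane time constant, and total subthreshold conductance from
  current-clamp sweeps; `discrepancy()` as a tuning objective.
- **I/O and presets** — YAML configurations (`load_config()`,
  `save_config()`), 14 frozen presets (`preset_names()`,
  `load_preset()`), plain-text trace/spike/sweep files, and
  `make_fixtures()` for deterministic synthetic test data.

Preset names (`fig3_bistable`, `fig4_disease`, `fig5_network_neuron`,
`fig6_*`, `s2fig_resonator`) refer to the figures of the source article
they reproduce. Their parameters were tuned once against those panels
and are frozen; `fig6_reference_currents()` lists, for each behavior
preset, the step current at which it shows its nominal label and the
higher current at which it enters depolarization block.

## Command-line interface

A thin CLI wraps the main workflows:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "metaneuron.R", package = "metaneuron"))') \
    <simulate|phase|sweep-alpha|network|classify|fit|make-fixtures> \
    --config FILE_OR_PRESET [--out DIR] [--seed N] [--dt MS]
```

`--config` accepts either a YAML file or a shipped preset name. All
outputs are plain text with `#`-prefixed provenance headers (seed,
parameters). Errors exit nonzero with a one-line `error:` diagnostic.

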