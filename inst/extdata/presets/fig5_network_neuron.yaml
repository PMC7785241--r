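# Asynchronous-irregular 1000-neuron eLIF network: at alpha = 1 the
# background state has a median rate near 2 Hz, ISI CV near 0.8 and mean
# pairwise correlation well below 1/N; the homeostasis table keeps the
# background rate fixed as alpha declines while the response to the
# 1400-1650 ms stimulus window shrinks from tonic to truncated.
model:
  type: elif
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -60.0
  Ef: -60.0
  Ed: -40.0
  Vth: -50.0
  Vr: -65.0
  eps0: 1.0
  epsc: 0.12
  alpha: 1.0
  tau_e: 300.0
  delta: 0.04
  Ie_baseline: 0.0
protocol:
  duration: 5500.0
network:
  "N": 1000
  exc_fraction: 0.8
  density: 0.1
  wE: 10.0
  wI: 120.0
  delay: 1.5
  tau_syn: 2.0
  bg_rate: 520.0
  bg_weight: 80.0
  stimulus:
    n_targets: 100
    rate_multiplier: 3.0
    window:
    - 1400.0
    - 1650.0
  homeostasis:
  - alpha: 1.0
    wE_scale: 1.0
    Vth_shift: 0.0
    Vr_shift: 0.0
  - alpha: 0.85
    wE_scale: 1.0
    Vth_shift: 0.35
    Vr_shift: 0.35
  - alpha: 0.7
    wE_scale: 1.0
    Vth_shift: 0.75
    Vr_shift: 0.75
seeds:
  network: 42
  simulation: 1
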