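# Resonator-like eLIF regime (Eu < E0): energy depletion hyperpolarizes,
# giving dampened oscillations around the resting state
model:
  type: elif
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -72.0
  Ef: -60.0
  Ed: -30.0
  Vth: -50.0
  Vr: -65.0
  eps0: 1.0
  epsc: 0.1
  alpha: 1.0
  tau_e: 100.0
  delta: 0.05
  Ie_baseline: 0.0
protocol:
  duration: 2000.0
  segments:
  - start: 500.0
    stop: 1500.0
    amplitude: 30.0
seeds:
  simulation: 1
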