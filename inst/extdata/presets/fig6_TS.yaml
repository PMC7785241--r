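# Transient spiking: subthreshold adaptation silences the cell after a
# few onset spikes; the silent membrane sits below the flex potential,
# so the energy pool recovers for the rest of the step.
model:
  type: madexp
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -65.0
  Ef: -48.0
  Ed: -5.0
  Vth: -50.0
  Vr: -58.0
  eps0: 1.0
  epsc: 0.3
  alpha: 1.0
  tau_e: 300.0
  delta: 0.06
  Ie_baseline: 0.0
  DeltaT: 2.0
  Vpeak: 0.0
  a: 8.0
  b: 30.0
  tau_w: 400.0
  gamma: 5000.0
  I_KATP: 0.0
protocol:
  duration: 1700.0
  segments:
  - start: 200.0
    stop: 1200.0
    amplitude: 230.0
seeds:
  simulation: 1
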