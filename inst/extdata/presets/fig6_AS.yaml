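# Adaptive spiking: with Eu = E0 the leak does not creep, so the
# declining energy (falling gate gain) lengthens the ISIs.
model:
  type: madexp
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -65.0
  Ef: -60.0
  Ed: -5.0
  Vth: -50.0
  Vr: -58.0
  eps0: 1.0
  epsc: 0.3
  alpha: 1.0
  tau_e: 300.0
  delta: 0.005
  Ie_baseline: 0.0
  DeltaT: 2.0
  Vpeak: 0.0
  a: 0.0
  b: 0.0
  tau_w: 200.0
  gamma: 500.0
  I_KATP: 0.0
protocol:
  duration: 1700.0
  segments:
  - start: 200.0
    stop: 1200.0
    amplitude: 300.0
seeds:
  simulation: 1
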