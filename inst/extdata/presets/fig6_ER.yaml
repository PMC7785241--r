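# Post-excitatory rebound: a weak depolarizing step stays subthreshold
# (energy depletion lowers the leak), while amplifying adaptation
# (a < 0) charges slowly; at offset the energy overshoot plus residual
# inward adaptation ignite rebound spikes.
model:
  type: madexp
  Cm: 200.0
  gL: 10.0
  E0: -58.0
  Eu: -75.0
  Ef: -58.0
  Ed: -18.0
  Vth: -52.0
  Vr: -58.0
  eps0: 1.0
  epsc: 0.3
  alpha: 1.0
  tau_e: 150.0
  delta: 0.02
  Ie_baseline: 0.0
  DeltaT: 2.0
  Vpeak: 0.0
  a: -18.0
  b: 0.0
  tau_w: 400.0
  gamma: 5000.0
  I_KATP: 0.0
protocol:
  duration: 1200.0
  segments:
  - start: 200.0
    stop: 700.0
    amplitude: 22.0
seeds:
  simulation: 1
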