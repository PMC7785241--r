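# eLIF cell whose declining energetic health traverses four stages:
# single-rest -> bistable -> tonic-spiking (hyperexcitable) -> energy-blocked
model:
  type: elif
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -55.0
  Ef: -60.0
  Ed: -20.0
  Vth: -58.0
  Vr: -68.0
  eps0: 1.0
  epsc: 0.2
  alpha: 1.0
  tau_e: 500.0
  delta: 0.02
  Ie_baseline: 0.0
protocol:
  duration: 1000.0
seeds:
  simulation: 1
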