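# Bistable eLIF cell: three fixed points at baseline current
# (up-state: low energy / depolarized; down-state: high energy / hyperpolarized)
model:
  type: elif
  Cm: 200.0
  gL: 10.0
  E0: -65.0
  Eu: -50.0
  Ef: -62.0
  Ed: -22.0
  Vth: -55.0
  Vr: -65.0
  eps0: 1.0
  epsc: 0.3
  alpha: 1.0
  tau_e: 500.0
  delta: 0.05
  Ie_baseline: 0.0
protocol:
  duration: 3000.0
  segments:
  - start: 500.0
    stop: 1500.0
    amplitude: 30.0
seeds:
  simulation: 1
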