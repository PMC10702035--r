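mechanism: dependent
level: low
setting: observed
targets:
  p_conf_any: 0.2
  p_exposure: 0.1
  p_any: 0.25
  p_petown: 0.1
  p_ante: 0.125
slopes:
  nu:
  - 0.5
  - -0.3
  - -0.03
  tau:
  - 0.5
  - -0.3
  - -0.03
  omega:
  - 0.5
  - -0.3
  - -0.03
intercepts:
  nu0: -1.079522473702477
  tau0: -0.953665788262543
  tau4: 0.921168087971489
  omega0: -1.577810992176321
  omega4: 1.550156376778305
rates: ~
calibrated: yes
achieved:
  p_conf_any: 0.2
  p_exposure: 0.100000000000001
  p_any: 0.250000000000003
calibration:
  tol: 0.005
  seed: 20240901.0
  n_ref: 200000.0
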