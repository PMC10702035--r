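p_eth: 0.732
delta:
- 31.367999999999999
- 1.0
sigma: 4.779
zeta:
- -1.23107
- 0.03
- 0.2
eta:
- -1.30174
- 0.06
- 0.5
iota:
- 1.67695
- 0.3
kappa:
- -2.67164
- 0.08
- 0.1
- 0.0
- -0.1
- 0.0
lambda:
- -5.35422
- 0.15
- 0.1
- 0.0
- -0.2
- 0.0
rho:
- -1.72615
- 0.076752836433135
- 0.5
- 0.1
- -0.1
- 0.1
- 0.2
- 0.3
psi:
- -1.33345
- 0.076752836433135
- 0.3
- -0.2
- 0.3
- 0.0
- -0.1
- -0.2
phi:
- -2.02863
- 0.076752836433135
- -0.4
- 0.1
- -0.1
- 0.0
- 0.1
- 0.2
- -0.2
- -0.3
theta:
- -2.99779
- 0.693147180559945
- -0.3
- 0.5
- -0.2
- -0.2
- 0.15
- 0.3
theta_int: 0.0
setting: enhanced
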