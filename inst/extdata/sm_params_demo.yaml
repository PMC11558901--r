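beta_x: 1.0986123
beta0: -3.9454
eta:
- -0.6
- 0.3
- 0.2
- -0.2
zeta:
- -0.2179
- 0.25
- 0.2
- 0.3
- 0.15
xi2: 0.8732
beta_rest:
- 0.4
- 0.3
- 0.25
- 0.2
theta_a1:
- -1.3
- 1.5
- 0.3
- 0.2
- 0.1
- 0.15
- 0.1
theta_a2:
- -1.6
- 1.8
- 0.35
- 0.15
- 0.12
- 0.1
- 0.08
omega:
- -1.9
- 0.5
- 0.6
- 1.5
- 0.3
- 0.2
- 0.1
- 0.1
- 0.1
psi:
- 2.4
- -0.4
- -0.4
- -0.5
- -0.3
delta_sm: 7.85
pz:
- 0.4
- 0.3
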