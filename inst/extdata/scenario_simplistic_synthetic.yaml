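name: simplistic-synthetic
covariates:
- name: X1
  family: normal
  intercept: 0.0
  dep: ~
- name: X2
  family: normal
  intercept: 0.0
  dep: ~
- name: X3
  family: normal
  intercept: 0.0
  dep: ~
- name: X4
  family: normal
  intercept: 0.0
  dep: ~
- name: X5
  family: normal
  intercept: 0.0
  dep: ~
- name: X6
  family: bernoulli
  intercept: 0.0
  dep: ~
- name: X7
  family: bernoulli
  intercept: 0.0
  dep: ~
- name: X8
  family: bernoulli
  intercept: 0.0
  dep: ~
- name: X9
  family: bernoulli
  intercept: 0.0
  dep: ~
exposure:
  intercept: -0.5
  coefs:
    X1: 0.4
    X2: -0.4
    X3: 0.3
    X5: 0.35
    X6: 0.5
    X7: -0.5
outcome:
  intercept: -0.9
  z_coef: 0.5
  terms:
  - cov: X1
    type: linear
    coef: 0.5
  - cov: X2
    type: linear
    coef: 0.4
  - cov: X3
    type: linear
    coef: -0.4
  - cov: X5
    type: linear
    coef: 0.3
  - cov: X6
    type: linear
    coef: 0.6
  - cov: X8
    type: linear
    coef: -0.5
  interactions: []
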