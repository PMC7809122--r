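name: realistic-synthetic
covariates:
- name: X1
  family: normal
  intercept: 0.0
  dep: ~
- name: X2
  family: bernoulli
  intercept: 0.0
  dep:
    X1: 0.5
- name: X3
  family: normal
  intercept: 0.0
  dep:
    X1: 0.4
    X2: -0.3
- name: X4
  family: bernoulli
  intercept: -0.3
  dep:
    X3: 0.4
- name: X5
  family: normal
  intercept: 0.0
  dep:
    X2: 0.5
    X4: 0.3
- name: X6
  family: normal
  intercept: 0.0
  dep:
    X5: 0.3
- name: X7
  family: bernoulli
  intercept: 0.2
  dep:
    X6: -0.4
    X2: 0.3
- name: X8
  family: normal
  intercept: 0.0
  dep:
    X7: 0.4
    X1: -0.2
- name: X9
  family: normal
  intercept: 0.0
  dep:
    X3: 0.3
    X8: 0.2
- name: X10
  family: bernoulli
  intercept: -0.2
  dep:
    X9: 0.3
- name: X11
  family: normal
  intercept: 0.0
  dep:
    X10: 0.2
    X5: 0.2
- name: X12
  family: normal
  intercept: 0.0
  dep:
    X11: 0.3
- name: X13
  family: bernoulli
  intercept: 0.1
  dep:
    X12: 0.3
    X4: -0.3
- name: X14
  family: normal
  intercept: 0.0
  dep:
    X13: 0.2
    X9: 0.3
- name: X15
  family: normal
  intercept: 0.0
  dep:
    X14: 0.25
    X7: -0.2
- name: X16
  family: bernoulli
  intercept: -0.1
  dep:
    X15: 0.4
- name: X17
  family: normal
  intercept: 0.0
  dep:
    X16: 0.3
    X11: 0.2
- name: X18
  family: bernoulli
  intercept: 0.0
  dep:
    X17: 0.2
- name: X19
  family: normal
  intercept: 0.0
  dep:
    X18: 0.2
    X13: 0.25
- name: X20
  family: normal
  intercept: 0.0
  dep:
    X19: 0.3
- name: X21
  family: bernoulli
  intercept: -0.2
  dep:
    X20: 0.3
    X16: 0.2
- name: X22
  family: normal
  intercept: 0.0
  dep:
    X21: 0.2
    X17: 0.2
exposure:
  intercept: -0.4
  coefs:
    X1: 0.35
    X3: 0.3
    X5: -0.3
    X6: 0.3
    X8: 0.25
    X10: 0.45
    X14: -0.25
    X16: 0.4
    X19: 0.3
    X21: -0.35
outcome:
  intercept: -1.0
  z_coef: 0.45
  terms:
  - cov: X1
    type: linear
    coef: 0.4
  - cov: X5
    type: linear
    coef: 0.35
  - cov: X10
    type: linear
    coef: 0.5
  - cov: X16
    type: linear
    coef: -0.45
  - cov: X3
    type: quadratic
    coef: 0.25
    center: 0.0
  - cov: X8
    type: quadratic
    coef: -0.2
    center: 0.0
  - cov: X14
    type: quadratic
    coef: 0.2
    center: 0.0
  - cov: X6
    type: step
    coef: 0.5
    threshold: 0.0
  - cov: X19
    type: step
    coef: -0.45
    threshold: 0.5
  interactions:
  - cov: X1
    coef: 0.3
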