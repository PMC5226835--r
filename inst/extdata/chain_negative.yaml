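name: chain_neg_ma_conv_n9
species:
- name: S1
  domain: concentration
- name: S2
  domain: concentration
- name: S3
  domain: concentration
- name: S4
  domain: concentration
stoichiometry:
- - 1
  - -1
  - -1
  - 0
  - 0
  - 0
  - 0
  - 0
- - 0
  - 1
  - 0
  - -1
  - -1
  - 0
  - 0
  - 0
- - 0
  - 0
  - 0
  - 1
  - 0
  - -1
  - -1
  - 0
- - 0
  - 0
  - 0
  - 0
  - 0
  - 1
  - 0
  - -1
flows:
- rate_coefficient: k1
  factors: []
- rate_coefficient: k2
  factors:
  - type: power
    species: S1
    exponent: 1.0
  - type: hill_inhibition
    species: S4
    constant: kn1
    exponent: 'n'
  regulators:
  - S4
- rate_coefficient: k3
  factors:
  - type: power
    species: S1
    exponent: 1.0
- rate_coefficient: k4
  factors:
  - type: power
    species: S2
    exponent: 1.0
- rate_coefficient: k5
  factors:
  - type: power
    species: S2
    exponent: 1.0
- rate_coefficient: k6
  factors:
  - type: power
    species: S3
    exponent: 1.0
- rate_coefficient: k7
  factors:
  - type: power
    species: S3
    exponent: 1.0
- rate_coefficient: k8
  factors:
  - type: power
    species: S4
    exponent: 1.0
nl_parameters:
- name: kn1
  role: regulation
cooperativity:
  'n': 9.0
moieties: []
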