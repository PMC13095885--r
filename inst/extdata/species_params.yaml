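# Species-generic parameters of the expolinear-logistic individual leaf
# size model, per trait. Units: mm (L1, dsl), mm per leaf (cm), per leaf
# (rm, dr), leaf positions (tb, xs), TLN (breakpoints). se: standard errors.
shape_factors:
  standard: 0.71
  flag: 0.635
maize:
  blade_length:
    fixed: {L1: 51.18, cm: 123.84, rm: 1.17, tb: 2.02, dsl: 12.53}
    se:    {L1: 0.79, cm: 3.1, rm: 0.12, tb: 1.14, dsl: 1.49}
    xs_rule: {type: linear, a: 1.10, b: 0.47, se: {a: 0.55, b: 0.03}}
    dr_rule: {a: 2.88, b: -0.13, bp: 17.63, se: {a: 0.30, b: 0.02, bp: 0.34}}
  blade_width:
    fixed: {L1: 15.98, cm: 19.37, rm: 0.58, tb: 4.10, dsl: 0.20}
    se:    {L1: 0.06, cm: 1.7, rm: 0.05, tb: 0.40, dsl: 0.04}
    xs_rule: {type: linear, a: 5.97, b: 0.25, se: {a: 0.55, b: 0.03}}
    dr_rule: {a: 7.81, b: -0.41, bp: 17.13, se: {a: 0.8, b: 0.05, bp: 0.22}}
sorghum:
  blade_length:
    fixed: {L1: 17.59, cm: 70.5, rm: 1.56, tb: 1.92, dsl: 3.50}
    se:    {L1: 0.79, cm: 1.45, rm: 0.15, tb: 0.17, dsl: 0.70}
    xs_rule: {type: segmented, a: 4.64, b: 0.46, c: 0.26, bp: 20.50,
              se: {a: 0.72, b: 0.04, c: 0.02}}
    dr_rule: {a: 2.62, b: -0.08, bp: 27.02, se: {a: 0.2, b: 0.01, bp: 1.36}}
  blade_width:
    fixed: {L1: 4.20, cm: 11.72, rm: 0.61, tb: 4.04, dsl: 0.18}
    se:    {L1: 0.06, cm: 0.21, rm: 0.02, tb: 0.15, dsl: 0.03}
    xs_rule: {type: segmented, a: 7.31, b: 0.25, c: 0.20, bp: 20.50,
              se: {a: 0.76, b: 0.04, c: 0.02}}
    dr_rule: {a: 1.78, b: -0.05, bp: 29.00, se: {a: 0.18, b: 0.01, bp: 2.9}}
pearl_millet:
  blade_length:
    fixed: {L1: 34.51, cm: 62.69, rm: 0.92, tb: 1.53, dsl: 1.37}
    se:    {L1: 0.79, cm: 3.14, rm: 0.12, tb: 0.28, dsl: 0.41}
    xs_rule: {type: linear, a: 7.16, b: 0.31, se: {a: 0.5, b: 0.03}}
    dr_rule: {a: 5.15, b: -0.22, bp: 19.87, se: {a: 0.71, b: 0.04, bp: 0.9}}
  blade_width:
    fixed: {L1: 7.06, cm: 14.99, rm: 0.19, tb: 14.79, dsl: 0.08}
    se:    {L1: 0.06, cm: 3.14, rm: 0.02, tb: 1.69, dsl: 0.02}
    xs_rule: {type: linear, a: 5.11, b: 0.40, se: {a: 3.63, b: 0.17}}
    dr_rule: {a: 2.97, b: -0.11, bp: 22.00, se: {a: 4.04, b: 0.21, bp: 8.13}}
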