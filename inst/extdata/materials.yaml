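# Second-order polynomial hyperelastic parameters for breast tissue,
# from published ex vivo breast tissue measurements.  Coefficients are
# interpreted on the MPa scale (see package vignette); compressibility
# coefficients are derived from the Poisson ratio when omitted.
unit: MPa
poisson_ratio: 0.495
density: 1000
tissues:
  tumor:            # malignant tumor
    c10: 1.41e-3
    c01: 1.41e-3
    c11: 0.171
    c20: 1.66e-2
    c02: 1.66e-2
  benign:           # benign breast tissue
    c10: 0.375e-3
    c01: 0.375e-3
    c11: 2.56e-3
    c20: 0.283e-3
    c02: 0.283e-3
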