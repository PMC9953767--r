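{
  "bundle": "qeegnorm-normative-v1",
  "notes": "Normative age regressions for eye-closed resting-state EEG in the double-banana bipolar montage, healthy cohort N = 37, ages 10-73. Polynomial coefficients in increasing power order; exp_decay is value = a + b*exp(-c*age) with coefficients [a, b, c].",
  "equations": [
    {
      "feature": "pdr.freq.left",
      "kind": "polynomial",
      "coefficients": [9.77, 0.03, -0.0004, -0.000002],
      "r": 0.2977,
      "n": 37,
      "age_range": [10, 73],
      "units": "Hz"
    },
    {
      "feature": "pdr.freq.right",
      "kind": "polynomial",
      "coefficients": [9.77, 0.03, -0.0004, -0.000002],
      "r": 0.2977,
      "n": 37,
      "age_range": [10, 73],
      "units": "Hz"
    },
    {
      "feature": "pdr.amp.left",
      "kind": "exp_decay",
      "coefficients": [14.62, 99.31, 0.127],
      "r": 0.7011,
      "n": 37,
      "age_range": [10, 73],
      "units": "uV"
    },
    {
      "feature": "pdr.amp.right",
      "kind": "exp_decay",
      "coefficients": [14.62, 99.32, 0.127],
      "r": 0.689,
      "n": 37,
      "age_range": [10, 73],
      "units": "uV"
    },
    {
      "feature": "sse.F_left",
      "kind": "polynomial",
      "coefficients": [3.2247, 0.1128, -0.0027, 0.00002],
      "r": 0.3242,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    },
    {
      "feature": "sse.F_right",
      "kind": "polynomial",
      "coefficients": [3.0516, 0.1374, -0.0034, 0.00002],
      "r": 0.315,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    },
    {
      "feature": "sse.PO_left",
      "kind": "polynomial",
      "coefficients": [3.3885, 0.0726, -0.0012, 0.000005],
      "r": 0.3718,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    },
    {
      "feature": "sse.PO_right",
      "kind": "polynomial",
      "coefficients": [2.7445, 0.1229, -0.0025, 0.000015],
      "r": 0.4638,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    },
    {
      "feature": "sse.T_left",
      "kind": "polynomial",
      "coefficients": [3.9949, 0.0589, -0.0014, 0.0000096],
      "r": 0.2515,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    },
    {
      "feature": "sse.T_right",
      "kind": "polynomial",
      "coefficients": [3.408, 0.0994, -0.0023, 0.000015],
      "r": 0.3658,
      "n": 37,
      "age_range": [10, 73],
      "units": "bits"
    }
  ]
}
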