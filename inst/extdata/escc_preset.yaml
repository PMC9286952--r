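# Synthetic ESCC-like cohort preset: truncated-normal marginals for the
# blood indicators and continuous age, categorical stage codes with the
# published proportions, and a logistic label signal planted on the eleven
# jointly prognostic indicators. Coefficients are engineering choices
# scaled for a Bayes accuracy around 0.9.
n_patients: 298
target_positive_count: 147
label_name: survival5y
seed: 1
indicators:
  - {name: BASO,  mean: 0.050,   sd: 0.118,  min: 0.0,     max: 1.0}
  - {name: EO,    mean: 0.144,   sd: 0.272,  min: 0.0,     max: 3.0}
  - {name: FIB,   mean: 379.262, sd: 30.398, min: 167.613, max: 909.725}
  - {name: PLT,   mean: 226.289, sd: 7.931,  min: 45.0,    max: 448.0}
  - {name: ALB,   mean: 42.077,  sd: 5.005,  min: 27.0,    max: 59.0}
  - {name: HGB,   mean: 137.742, sd: 15.074, min: 95.0,    max: 189.0}
  - {name: WBC,   mean: 6.564,   sd: 2.019,  min: 2.18,    max: 15.3}
  - {name: MONO,  mean: 0.406,   sd: 0.301,  min: 0.0,     max: 1.0}
  - {name: APTT,  mean: 35.929,  sd: 7.904,  min: 15.4,    max: 78.5}
  - {name: GLOB,  mean: 29.077,  sd: 5.122,  min: 17.0,    max: 45.0}
  - {name: RBC,   mean: 4.452,   sd: 0.473,  min: 2.93,    max: 6.04}
  - {name: PT,    mean: 10.322,  sd: 1.684,  min: 7.0,     max: 16.5}
  - {name: LYMPH, mean: 1.930,   sd: 0.692,  min: 0.0,     max: 8.0}
  - {name: NEUT,  mean: 3.864,   sd: 1.682,  min: 0.0,     max: 10.6}
  - {name: TP,    mean: 71.070,  sd: 7.209,  min: 50.0,    max: 92.0}
  - {name: INR,   mean: 0.796,   sd: 0.185,  min: 0.45,    max: 1.64}
  - {name: TT,    mean: 15.569,  sd: 2.575,  min: 1.3,     max: 46.5}
  - {name: Age,   mean: 58.0,    sd: 9.5,    min: 38.0,    max: 82.0}
categoricals:
  T_stage:   {"1": 42, "2": 89, "3": 165, "4": 2}
  N_stage:   {"0": 170, "1": 80, "2": 34, "3": 14}
  TNM_stage: {"1": 37, "2": 139, "3": 106, "4": 16}
signal_features: [TNM_stage, BASO, Age, PT, FIB, LYMPH, RBC, TT, PLT, T_stage, GLOB]
signal_coefficients: [2.34, 1.62, 1.62, 1.44, 1.44, -1.44, -1.44, 1.26, 1.26, 1.80, 1.26]
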