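{
  "comment": "PPV calculation task: COVID-19 antigen test. Prevalence is a required analysis input; the value here, with sensitivity 0.90 and specificity 0.99, yields PPV = 26.06% and renders as '36 out of 40 diseased test positive' in a reference population of 10256.",
  "sensitivity": 0.90,
  "specificity": 0.99,
  "prevalence": 0.0039,
  "nf_population": 10256,
  "classifier": {
    "correct_center": 26,
    "correct_halfwidth": 5,
    "sens_anchor": 90,
    "spec_anchor": 99,
    "confusion_halfwidth": 1,
    "noninfo_halfwidth": 5
  }
}
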