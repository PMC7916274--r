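# Synthetic national aggregation parameters (illustrative magnitudes for a
# large middle-income country, 2015; NOT official statistics). PV/QV, PH/QH
# and PM/QM are left out so they are estimated from the survey panel.
POP: 430.0e+6                  # population aged 45+ (persons)
official_the_all_ages: 625.0e+9   # official all-age total health expenditure (2015 USD)
share_45plus: 0.5999           # share of national health spending by ages 45+
n_smokers_45plus: 200.0e+6     # current + former smokers aged 45+
n_smokers_by_service:          # service-specific smoker denominators
  outpatient: 61.0e+6
  inpatient: 38.0e+6
  selfmed: 100.0e+6
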