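# Default model parameter registry: screening volumes, device effects,
# test performance, flow probabilities and 2014 USD unit costs.
# Percentages are stored as fractions in [0, 1]; currency in 2014 USD.
# low95/high95 are 95% interval bounds (2.5th/97.5th percentiles).
parameters:
  - name: women_tested_annual
    distribution: normal
    mean: 723829
    low95: 583056
    high95: 869393
    units: women/year
    source: Table 1
  - name: or_endocervical_broom
    distribution: normal
    mean: 1.57
    low95: 1.44
    high95: 1.70
    units: odds ratio
    source: Table 1
  - name: or_detection_endocervical
    distribution: normal
    mean: 1.89
    low95: 1.80
    high95: 1.98
    units: odds ratio
    source: Table 1
  - name: or_detection_severe
    distribution: normal
    mean: 2.46
    low95: 1.75
    high95: 3.17
    units: odds ratio
    source: Table 1
  - name: hiv_positive_fraction
    distribution: proportion
    mean: 0.51
    low95: 0.40
    high95: 0.64
    units: fraction of women tested
    source: Table 1
  - name: hiv_women_tested_annual
    distribution: normal
    mean: 372340
    low95: 261707
    high95: 493988
    units: women/year
    source: Table 1
  - name: abnormal_fraction
    distribution: proportion
    mean: 0.73
    low95: 0.71
    high95: 0.75
    units: fraction of all smears
    source: Table 1
  - name: hsil_fraction
    distribution: proportion
    mean: 0.31
    low95: 0.29
    high95: 0.33
    units: fraction of all smears
    source: Table 1
  - name: lsil_fraction
    distribution: proportion
    mean: 0.37
    low95: 0.35
    high95: 0.39
    units: fraction of all smears
    source: Table 1
  - name: ascus_fraction
    distribution: proportion
    mean: 0.05
    low95: 0.04
    high95: 0.06
    units: fraction of all smears
    source: Table 1
  - name: endocervical_spatula
    distribution: proportion
    mean: 0.53
    low95: 0.52
    high95: 0.54
    units: fraction of all smears
    source: Table 1
  - name: endocervical_broom
    distribution: proportion
    mean: 0.83
    low95: 0.76
    high95: 0.90
    units: fraction of all smears
    source: Table 1
  - name: sens_endocervical
    distribution: proportion
    mean: 0.76
    low95: 0.72
    high95: 0.80
    units: probability
    source: Table 1
  - name: sens_no_endocervical
    distribution: proportion
    mean: 0.40
    low95: 0.35
    high95: 0.45
    units: probability
    source: Table 1
  - name: sens_no_endocervical_hsil
    distribution: proportion
    mean: 0.32
    low95: 0.23
    high95: 0.44
    units: probability
    source: Table 1
  - name: repeat_done
    distribution: proportion
    mean: 0.90
    low95: 0.85
    high95: 0.95
    units: fraction of returning patients
    source: Table 1
  - name: satisfactory
    distribution: proportion
    mean: 0.98
    low95: 0.98
    high95: 0.99
    units: fraction of all smears
    source: Table 1
  - name: specificity
    distribution: proportion
    mean: 0.84
    low95: 0.81
    high95: 0.87
    units: probability
    source: Table 1
  - name: lost_to_follow_up
    distribution: proportion
    mean: 0.08
    low95: 0.06
    high95: 0.10
    units: fraction of recalled patients
    source: Table 1
  - name: usd_zar_rate
    distribution: point
    mean: 0.09
    units: USD per ZAR
    source: Table 2
  - name: cost_spatula
    distribution: point
    mean: 0.02
    units: USD per device
    source: Table 2
  - name: cost_broom
    distribution: point
    mean: 0.22
    units: USD per device
    source: Table 2
  - name: cost_visit
    distribution: point
    mean: 8.36
    units: USD per outpatient visit
    source: Table 2
  - name: cost_lab
    distribution: point
    mean: 4.89
    units: USD per cytology test
    source: Table 2
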