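cohort_size: 1000.0
entry_age: 41.0
horizon_age: 90.0
male_fraction: 0.52
quit_rate:
  NRT: 0.099
  EC: 0.18
quit_rate_se:
  NRT: 0.014
  EC: 0.017
first_cycle_death_prob:
  NRT: 0.002237136465
  EC: 0.002277904328
first_cycle_cost:
  NRT: 1116.0
  EC: 1174.0
first_cycle_cost_se:
  NRT: 163.0
  EC: 147.0
first_cycle_qaly:
  NRT: 0.882
  EC: 0.886
first_cycle_qaly_se:
  NRT: 0.009
  EC: 0.008
relapse_prob: 0.1
relapse_prob_se: 0.0306
relapse_years: 10.0
mortality:
- sex: male
  age_min: 35.0
  smoker: 0.0024
  smoker_se: 0.004
  ex_smoker: 0.0018
  ex_smoker_se: 0.0035
- sex: male
  age_min: 45.0
  smoker: 0.008
  smoker_se: 0.004
  ex_smoker: 0.0051
  ex_smoker_se: 0.0073
- sex: male
  age_min: 55.0
  smoker: 0.0194
  smoker_se: 0.0052
  ex_smoker: 0.0124
  ex_smoker_se: 0.0058
- sex: male
  age_min: 65.0
  smoker: 0.0515
  smoker_se: 0.0082
  ex_smoker: 0.0308
  ex_smoker_se: 0.0059
- sex: male
  age_min: 75.0
  smoker: 0.2536
  smoker_se: 0.0204
  ex_smoker: 0.1512
  ex_smoker_se: 0.0114
- sex: female
  age_min: 35.0
  smoker: 0.0014
  smoker_se: 0.0031
  ex_smoker: 0.0011
  ex_smoker_se: 0.0027
- sex: female
  age_min: 45.0
  smoker: 0.0053
  smoker_se: 0.0033
  ex_smoker: 0.0034
  ex_smoker_se: 0.0059
- sex: female
  age_min: 55.0
  smoker: 0.013
  smoker_se: 0.0043
  ex_smoker: 0.0083
  ex_smoker_se: 0.0048
- sex: female
  age_min: 65.0
  smoker: 0.0345
  smoker_se: 0.0068
  ex_smoker: 0.0206
  ex_smoker_se: 0.0049
- sex: female
  age_min: 75.0
  smoker: 0.2079
  smoker_se: 0.019
  ex_smoker: 0.124
  ex_smoker_se: 0.0105
annual_cost:
- sex: male
  age_min: 35.0
  smoker: 54.48
  smoker_se: 0.0
  ex_smoker: 16.57
  ex_smoker_se: 0.0
- sex: male
  age_min: 45.0
  smoker: 54.48
  smoker_se: 0.0
  ex_smoker: 16.57
  ex_smoker_se: 0.0
- sex: male
  age_min: 55.0
  smoker: 181.97
  smoker_se: 0.0
  ex_smoker: 64.99
  ex_smoker_se: 0.0
- sex: male
  age_min: 65.0
  smoker: 315.75
  smoker_se: 0.0
  ex_smoker: 83.82
  ex_smoker_se: 0.0
- sex: male
  age_min: 75.0
  smoker: 535.22
  smoker_se: 0.0
  ex_smoker: 105.36
  ex_smoker_se: 0.0
- sex: female
  age_min: 35.0
  smoker: 41.31
  smoker_se: 0.0
  ex_smoker: 10.72
  ex_smoker_se: 0.0
- sex: female
  age_min: 45.0
  smoker: 41.31
  smoker_se: 0.0
  ex_smoker: 10.72
  ex_smoker_se: 0.0
- sex: female
  age_min: 55.0
  smoker: 119.83
  smoker_se: 0.0
  ex_smoker: 40.95
  ex_smoker_se: 0.0
- sex: female
  age_min: 65.0
  smoker: 249.03
  smoker_se: 0.0
  ex_smoker: 71.25
  ex_smoker_se: 0.0
- sex: female
  age_min: 75.0
  smoker: 470.69
  smoker_se: 0.0
  ex_smoker: 103.18
  ex_smoker_se: 0.0
annual_utility:
- sex: male
  age_min: 35.0
  smoker: 0.889
  smoker_se: 0.007
  ex_smoker: 0.908
  ex_smoker_se: 0.005
- sex: male
  age_min: 45.0
  smoker: 0.841
  smoker_se: 0.007
  ex_smoker: 0.861
  ex_smoker_se: 0.005
- sex: male
  age_min: 55.0
  smoker: 0.78
  smoker_se: 0.008
  ex_smoker: 0.803
  ex_smoker_se: 0.005
- sex: male
  age_min: 65.0
  smoker: 0.756
  smoker_se: 0.008
  ex_smoker: 0.781
  ex_smoker_se: 0.006
- sex: male
  age_min: 75.0
  smoker: 0.71
  smoker_se: 0.009
  ex_smoker: 0.737
  ex_smoker_se: 0.006
- sex: female
  age_min: 35.0
  smoker: 0.87
  smoker_se: 0.007
  ex_smoker: 0.889
  ex_smoker_se: 0.004
- sex: female
  age_min: 45.0
  smoker: 0.83
  smoker_se: 0.007
  ex_smoker: 0.85
  ex_smoker_se: 0.005
- sex: female
  age_min: 55.0
  smoker: 0.763
  smoker_se: 0.008
  ex_smoker: 0.784
  ex_smoker_se: 0.005
- sex: female
  age_min: 65.0
  smoker: 0.751
  smoker_se: 0.008
  ex_smoker: 0.773
  ex_smoker_se: 0.006
- sex: female
  age_min: 75.0
  smoker: 0.676
  smoker_se: 0.009
  ex_smoker: 0.7
  ex_smoker_se: 0.007
discount_rate_cost: 0.035
discount_rate_qaly: 0.0
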