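# Reference normalization point.  Output, hedonic and total-cost means are
# the published 2011 Dutch general-hospital cross-section means; the input
# price means are SYNTHETIC (the source reports no price levels) and equal
# the package generator's defaults.  At the mean point all standardized
# prices are zero, so the synthetic price levels do not affect any
# evaluated elasticity or share.
base_year: 2003
outputs:
  admissions: 44767
  outpatients: 76347
  other_revenues: 14896
  er_visits: 24115
hedonics:
  surgery_ortho: 0.117
  psych_beds: 0.27
  ic_beds: 0.23
  expected_los: 3.3
  neurosurgery: 0.008
  cardiothoracic: 0.003
prices:
  man_adm: 48000
  nursing: 45000
  paramedical: 42000
  auxiliary: 30000
  material: 1.0
  capital: 11000
total_cost: 147.8e6
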