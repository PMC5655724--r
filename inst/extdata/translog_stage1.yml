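# Stage-1 parameter set of the Dutch general-hospital translog cost system
# (three services, full 2003-2011 panel).  Values as printed, three
# decimals; the loader re-derives the capital column so linear price
# homogeneity holds exactly (see ?repair_homogeneity).
constant: 0.203
year_2004: -0.035
year_2005: -0.056
year_2006: -0.081
year_2007: -0.095
year_2008: -0.123
year_2009: -0.138
year_2010: -0.146
year_2011: -0.172
admissions: 0.626
outpatients: 0.353
other_revenues: 0.089
admissions_x_admissions: -0.085
admissions_x_outpatients: 0.139
admissions_x_other_revenues: 0.019
outpatients_x_outpatients: -0.128
outpatients_x_other_revenues: -0.036
other_revenues_x_other_revenues: 0.010
price_man_adm: 0.116
price_nursing: 0.338
price_paramedical: 0.053
price_auxiliary: 0.093
price_material: 0.302
price_capital: 0.098
price_man_adm_x_price_man_adm: 0.016
price_man_adm_x_price_nursing: 0.094
price_man_adm_x_price_paramedical: 0.026
price_man_adm_x_price_auxiliary: -0.002
price_man_adm_x_price_material: -0.127
price_man_adm_x_price_capital: -0.007
price_nursing_x_price_nursing: -0.117
price_nursing_x_price_paramedical: 0.011
price_nursing_x_price_auxiliary: -0.041
price_nursing_x_price_material: 0.076
price_nursing_x_price_capital: -0.024
price_paramedical_x_price_paramedical: -0.014
price_paramedical_x_price_auxiliary: 0.015
price_paramedical_x_price_material: -0.041
price_paramedical_x_price_capital: 0.003
price_auxiliary_x_price_auxiliary: -0.008
price_auxiliary_x_price_material: 0.047
price_auxiliary_x_price_capital: -0.010
price_material_x_price_material: 0.063
price_material_x_price_capital: -0.018
price_capital_x_price_capital: 0.056
admissions_x_price_man_adm: -0.001
admissions_x_price_nursing: -0.022
admissions_x_price_paramedical: 0.011
admissions_x_price_auxiliary: -0.007
admissions_x_price_material: 0.028
admissions_x_price_capital: -0.009
outpatients_x_price_man_adm: 0.011
outpatients_x_price_nursing: 0.016
outpatients_x_price_paramedical: -0.001
outpatients_x_price_auxiliary: -0.003
outpatients_x_price_material: -0.038
outpatients_x_price_capital: 0.015
other_revenues_x_price_man_adm: -0.002
other_revenues_x_price_nursing: -0.003
other_revenues_x_price_paramedical: 0.006
other_revenues_x_price_auxiliary: -0.001
other_revenues_x_price_material: 0.004
other_revenues_x_price_capital: -0.004
trend_x_price_man_adm: 0.087
trend_x_price_nursing: 0.049
trend_x_price_paramedical: 0.061
trend_x_price_auxiliary: 0.028
trend_x_price_material: -0.251
trend_x_price_capital: 0.027
admissions_x_surgery_ortho: -0.163
admissions_x_psych_beds: 0.015
admissions_x_ic_beds: 0.033
admissions_x_expected_los: 0.254
admissions_x_neurosurgery: 0.034
admissions_x_cardiothoracic: 0.123
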