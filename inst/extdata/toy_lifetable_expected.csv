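quantity,scenario,value
life_years,baseline,3854.82693827
qaly,baseline,3720.87030644
cost_brl,baseline,1339566.31831
incident_cases,baseline,440.396857062
deaths,baseline,2400
life_years,intervention,3858.54823027
qaly,intervention,3733.61195233
cost_brl,intervention,1249362.77945
incident_cases,intervention,362.738937338
deaths,intervention,2400
pv_qaly_5pct,baseline,3618.905775526
pv_qaly_5pct,intervention,3631.090698753
pv_cost_5pct,baseline,1297893.831143195
pv_cost_5pct,intervention,1211315.144761243
survivors_cycle2_age61,baseline,966.758551151
survivors_cycle2_age62,baseline,764.730242395
survivors_cycle3_age62,baseline,923.338144729
cases_averted,delta,77.657919724
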