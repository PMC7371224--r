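approach,sex,age_group,prevalence_percent
total_risk,male,40-49,0.4
total_risk,male,50-59,0.1
total_risk,male,60-69,1.5
total_risk,male,ge70,7.0
total_risk,male,all,1.0
total_risk,female,40-49,0.0
total_risk,female,50-59,0.0
total_risk,female,60-69,0.0
total_risk,female,ge70,1.6
total_risk,female,all,0.1
total_risk,all,40-49,0.2
total_risk,all,50-59,0.1
total_risk,all,60-69,0.7
total_risk,all,ge70,4.3
total_risk,all,all,0.5
single_risk,male,40-49,17.1
single_risk,male,50-59,21.7
single_risk,male,60-69,30.5
single_risk,male,ge70,29.4
single_risk,male,all,22.1
single_risk,female,40-49,22.5
single_risk,female,50-59,30.6
single_risk,female,60-69,28.7
single_risk,female,ge70,33.7
single_risk,female,all,26.7
single_risk,all,40-49,20.2
single_risk,all,50-59,26.3
single_risk,all,60-69,29.5
single_risk,all,ge70,31.6
single_risk,all,all,24.6
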