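sex,age_group,population_thousands
male,40-49,9210
male,50-59,6303
male,60-69,3730
male,ge70,1881
female,40-49,9087
female,50-59,5662
female,60-69,3257
female,ge70,1638
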