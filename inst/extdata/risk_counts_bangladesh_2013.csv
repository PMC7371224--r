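category,men,women
very_low,1034,2081
low,1047,925
moderate,600,260
high,26,3
very_high,1,0
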