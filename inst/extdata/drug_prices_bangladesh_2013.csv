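drug,price_per_100_tablets_usd,tablets_per_day
aspirin,0.45,1
enalapril,2.38,1
hydrochlorothiazide,0.83,1
simvastatin,4.26,1
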