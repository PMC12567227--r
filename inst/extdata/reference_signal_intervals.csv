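drug,ror,ror_low,ror_high
everolimus,30.72,29.61,31.88
alpelisib,13.11,11.79,14.58
palbociclib,11.73,11.35,12.11
capivasertib,3.14,1.81,5.43
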