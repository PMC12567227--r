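drug,total_reports
capivasertib,1002
alpelisib,8038
palbociclib,110963
everolimus,35697
database,30179725
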