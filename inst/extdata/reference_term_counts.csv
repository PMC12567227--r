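term,capivasertib,alpelisib,palbociclib,everolimus
stomatitis,13,362,4103,3247
aphthous ulcer,0,22,218,279
mouth ulceration,0,24,374,558
lip ulceration,0,1,6,14
glossodynia,1,31,353,167
glossitis,0,4,53,28
cheilitis,0,16,103,74
oral pain,6,150,1242,775
gingival pain,1,17,215,79
oral discomfort,1,23,141,91
oropharyngeal pain,2,44,1119,344
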