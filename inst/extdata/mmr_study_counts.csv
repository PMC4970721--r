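"study","gene","count","sample_size"
"Ni 2015","MLH1",52,153
"Ni 2015","MSH2",22,153
"Ni 2015","MSH6",,153
"Ni 2015","PMS2",,153
"Sheng 2006","MLH1",8,21
"Sheng 2006","MSH2",4,21
"Sheng 2006","MSH6",0,21
"Sheng 2006","PMS2",,21
"Yan 2007","MLH1",,39
"Yan 2007","MSH2",,39
"Yan 2007","MSH6",4,39
"Yan 2007","PMS2",,39
"Sheng 2008","MLH1",,26
"Sheng 2008","MSH2",,26
"Sheng 2008","MSH6",,26
"Sheng 2008","PMS2",1,26
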