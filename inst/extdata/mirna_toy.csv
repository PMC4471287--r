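probe_id,class,L01,L02,L03,L04,L05,L06,L07,L08,L09,L10,L11
POS1,positive,500,500,500,500,500,500,500,500,500,500,500
POS2,positive,125,125,125,125,125,125,125,125,125,125,125
NEG1,negative,2,2,2,2,2,2,2,2,2,2,2
NEG2,negative,4,4,4,4,4,4,4,4,4,4,4
m1,endogenous,100,100,100,100,100,100,100,100,100,100,100
m2,endogenous,6,6,6,6,6,6,6,6,6,6,6
m3,endogenous,5,5,5,5,5,5,5,5,5,5,5
m4,endogenous,100,100,100,100,100,0,0,100,100,0,0
m5,endogenous,100,100,100,100,100,100,0,0,0,0,0
m6,endogenous,0,0,0,0,0,0,0,100,100,100,0
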