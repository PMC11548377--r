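class,FEAV,SAV,AB,OW
FEAV,10,0,0,0
SAV,88,775,17,0
AB,0,0,160,0
OW,11,88,6,2036
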