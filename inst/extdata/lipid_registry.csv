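name,charge,area,primary_phosphate,low_confidence
DPhPC,0,80,FALSE,FALSE
POPC,0,80,FALSE,FALSE
POPE,0,80,FALSE,FALSE
Sphingomyelin,0,80,FALSE,FALSE
POPA,-1,80,TRUE,FALSE
POPG,-1,80,FALSE,FALSE
POPS,-1,80,FALSE,FALSE
PI,-1,80,FALSE,FALSE
DPhPA,-1,80,TRUE,FALSE
DMPA,-1,80,TRUE,FALSE
DOPA,-1,80,TRUE,FALSE
BrPOPA,-1,80,TRUE,FALSE
DOPMe,-1,80,FALSE,TRUE
DOPEth,-1,80,FALSE,TRUE
Cardiolipin,-2,80,FALSE,FALSE
DOPP,-2,80,TRUE,TRUE
PIP,-3,80,TRUE,TRUE
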