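label,network,x,y,z
PCC,cDN,-3,-57,21
aMPFC,cDN,3,54,18
lAG,cDN,-48,-69,33
rAG,cDN,51,-63,27
dACC,SN,-3,15,42
lAI,SN,-36,15,6
rAI,SN,33,18,6
laPFC,SN,-27,45,30
raPFC,SN,30,42,30
lFEF,DAN,-24,-9,57
rFEF,DAN,27,-3,54
lIFG,DAN,-51,9,27
rIFG,DAN,54,12,30
lIPS,DAN,-42,-36,45
rIPS,DAN,39,-42,51
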