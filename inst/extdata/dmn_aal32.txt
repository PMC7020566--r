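ORBsup.L
ORBsup.R
MFG.L
MFG.R
ORBmid.L
ORBmid.R
REC.L
REC.R
ACG.L
ACG.R
PCG.L
PCG.R
PCUN.L
PCUN.R
HIP.L
HIP.R
PHG.L
PHG.R
IPL.L
IPL.R
ANG.L
ANG.R
STG.L
STG.R
TPOsup.L
TPOsup.R
MTG.L
MTG.R
TPOmid.L
TPOmid.R
ITG.L
ITG.R
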