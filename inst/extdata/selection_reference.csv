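feature,nca_rank,p_value,result
BSR,18,<0.001,Excluded
Magnitude,11,<0.001,Selected
SynchFastSlow,17,0.264,Excluded
BetaR,4,0.864,Excluded after t-test
DeltaR,5,<0.001,Selected
DAR,7,<0.001,Selected
DTABR,6,<0.001,Selected
BcSEF,1,<0.001,Selected
ExtraPR,19,0.675,Excluded
AlphaPR,12,0.439,Excluded
BetaPR,16,<0.001,Excluded
DeltaPR,3,0.014,Selected
ThetaPR,15,<0.001,Excluded
GammaPR,13,0.001,Excluded
ShannonEntropy,14,0.607,Excluded
LogEnergyEntropy,10,<0.001,Selected
SpectralEntropy,2,0.013,Selected
RenyiEntropy,8,<0.001,Selected
Ratio05,20,<0.001,Excluded
BG_Alpha_plus,9,<0.001,Selected
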