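residue,charge,pka
ASP,-1,3.65
GLU,-1,4.25
CYS,-1,8.50
TYR,-1,10.07
LYS,1,10.53
ARG,1,12.50
HIS,1,6.00
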