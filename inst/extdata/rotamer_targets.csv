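resid,nchi,chi1,chi2,chi3,chi4
ARG,4,-67,180,65,85
ASN,2,-65,-60,NA,NA
ASP,2,-70,-15,NA,NA
CYS,1,-65,NA,NA,NA
GLN,3,-67,180,-25,NA
GLU,3,-67,180,-10,NA
HIS,2,-65,-70,NA,NA
ILE,2,-65,170,NA,NA
LEU,2,-65,175,NA,NA
LYS,4,-67,180,180,180
MET,3,-67,180,75,NA
PHE,2,-65,90,NA,NA
PRO,2,-2.1,-12.3,NA,NA
SER,1,64,NA,NA,NA
THR,1,62,NA,NA,NA
TRP,2,-65,100,NA,NA
TYR,2,-65,90,NA,NA
VAL,1,175,NA,NA,NA
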