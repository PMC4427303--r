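source,sign,target,mechanism
HGF,+1,pMet,
pMet,+1,pGab1,
pGab1,+1,pPI3K,
pMet,+1,pPI3K,
pPI3K,+1,PIP3,
PIP3,+1,pAkt,
PDK1,+1,pAkt,
pMet,+1,pSOS,
pSOS,+1,aRas,
aRas,+1,pRaf1,
pRaf1,+1,pMEK,
pMEK,+1,pERK,
pERK,+1,RSK_s,
RSK_s,+1,RSK_d,
pERK,-1,pSOS,M01
RSK_d,-1,pSOS,M02
pERK,+1,pRaf1,M03
PIP3,+1,pGab1,M04
pAkt,-1,pRaf1,M05
pERK,+1,pPI3K,M06
aRas,+1,pPI3K,M07
PDK1,+1,pMEK,M08
pGab1,+1,pMEK,M09
pGab1,+1,pRaf1,M10
pERK,-1,pMEK,M11
PDK1,+1,RSK_d,M12
RSK_d,+1,aRas,M13
pMet,+1,aRac,M14
pMet,+1,pGab1,M15
aRac,+1,pPI3K,M16
pMet,+1,pPAK,M17
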