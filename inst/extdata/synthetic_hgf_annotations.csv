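source,target,type,modulates
pERK,pRaf1,independent,
PIP3,pGab1,independent,
pERK,pPI3K,independent,
aRas,pPI3K,independent,
PDK1,pMEK,independent,
pGab1,aRac,independent,
aRac,pPAK,independent,
pGab1,pPAK,independent,
PIP3,pPAK,independent,
aRas,pPAK,independent,
pPAK,pMEK,modulating,pRaf1
pPAK,pRaf1,modulating,aRas
pGab1,pMEK,modulating,pRaf1
pGab1,pRaf1,modulating,aRas
aRac,pMEK,modulating,pRaf1
aRac,pRaf1,modulating,aRas
aRas,pMEK,modulating,pRaf1
PIP3,pMEK,modulating,pRaf1
PIP3,pRaf1,modulating,aRas
PDK1,RSK_d,modulating,RSK_s
RSK_d,aRas,independent,
aRas,aRac,independent,
aRac,pPI3K,independent,
PIP3,aRac,independent,
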