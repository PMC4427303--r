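id,name,role
HGF,hepatocyte growth factor (stimulus),signal
pMet,Met receptor (phosphorylated),protein
pGab1,Gab1 adaptor (active),protein
pPI3K,PI3K (active),protein
PIP3,phosphatidylinositol-3-4-5-trisphosphate,protein
pAkt,Akt (phosphorylated S473),protein
pSOS,SOS1 (active),protein
aRas,Ras (GTP-bound),protein
pRaf1,Raf1 (active),protein
pMEK,MEK1/2 (phosphorylated S217/221),protein
pERK,ERK1/2 (dual phosphorylated),protein
RSK_s,p90RSK (single phosphorylated),protein
RSK_d,p90RSK (double phosphorylated; fully active),protein
aRac,Rac (GTP-bound),protein
pPAK,PAK (active),protein
PDK1,PDK1 (constitutively active),constant
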