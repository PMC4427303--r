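pair,inhibitors,species,early,late
ctrl vs Met_inh,Met_inh,pAkt,decrease,decrease
ctrl vs Met_inh,Met_inh,pMEK,decrease,decrease
ctrl vs Met_inh,Met_inh,pERK,decrease,decrease
ctrl vs Met_inh,Met_inh,RSK_s,decrease,decrease
ctrl vs Met_inh,Met_inh,RSK_d,decrease,decrease
ctrl vs Mek_inh,Mek_inh,pMEK,decrease,increase
ctrl vs Mek_inh,Mek_inh,pERK,decrease,decrease
ctrl vs Mek_inh,Mek_inh,RSK_s,decrease,decrease
ctrl vs Mek_inh,Mek_inh,RSK_d,decrease,decrease
ctrl vs Mek_inh,Mek_inh,pSOS,not_conclusive,increase
ctrl vs Mek_inh,Mek_inh,pAkt,not_conclusive,not_conclusive
ctrl vs ERK_siRNA,ERK_siRNA,pAkt,not_conclusive,not_conclusive
ctrl vs ERK_siRNA,ERK_siRNA,pMEK,not_conclusive,not_conclusive
ctrl vs Pdk_inh,Pdk_inh,pAkt,decrease,decrease
ctrl vs Pdk_inh,Pdk_inh,pMEK,decrease,increase
ctrl vs Pdk_inh,Pdk_inh,pERK,decrease,increase
ctrl vs Pdk_inh,Pdk_inh,RSK_s,decrease,increase
ctrl vs Pdk_inh,Pdk_inh,RSK_d,decrease,increase
ctrl vs Mek_inh+Pdk_inh,Mek_inh+Pdk_inh,pAkt,decrease,decrease
ctrl vs Mek_inh+Pdk_inh,Mek_inh+Pdk_inh,pMEK,decrease,increase
ctrl vs Mek_inh+Pdk_inh,Mek_inh+Pdk_inh,pERK,decrease,decrease
ctrl vs Mek_inh+Pdk_inh,Mek_inh+Pdk_inh,RSK_s,decrease,decrease
ctrl vs Mek_inh+Pdk_inh,Mek_inh+Pdk_inh,RSK_d,decrease,decrease
Pdk_inh vs Mek_inh+Pdk_inh,Mek_inh,pAkt,decrease,decrease
Mek_inh vs Mek_inh+Pdk_inh,Pdk_inh,pAkt,decrease,decrease
Mek_inh vs Mek_inh+Pdk_inh,Pdk_inh,pMEK,decrease,decrease
Mek_inh vs Mek_inh+Pdk_inh,Pdk_inh,RSK_d,decrease,decrease
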