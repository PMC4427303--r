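"parameter","log10_value"
"k_act_PIP3_by_pPI3K",0
"k_deact_PIP3",-0.5
"k_act_RSK_d_from_RSK_s",0
"k_deact_RSK_d",-0.5
"k_act_RSK_s_by_pERK",0
"k_deact_RSK_s",-0.5
"k_act_aRas_by_pSOS",0
"k_deact_aRas",-0.5
"k_act_pAkt_by_PDK1",0
"k_act_pAkt_by_PIP3",0
"k_deact_pAkt",-0.5
"k_act_pERK_by_pMEK",0
"k_deact_pERK",-0.5
"k_act_pGab1_by_pMet",0
"k_deact_pGab1",-0.5
"k_act_pMEK_by_pRaf1",0
"k_deact_pMEK",-0.5
"k_act_pMet_by_HGF",0
"k_deact_pMet",-0.5
"k_synth_pMet",-2
"k_deg_pMet_i",-2
"k_deg_pMet",-1
"k_act_pPI3K_by_pGab1",0
"k_act_pPI3K_by_pMet",0
"k_deact_pPI3K",-0.5
"k_act_pRaf1_by_aRas",0
"k_deact_pRaf1",-0.5
"k_act_pSOS_by_pMet",0
"k_deact_pSOS",-0.5
"k_act_pGab1_by_PIP3",-0.5
"k_act_pMEK_by_PDK1",-0.5
"k_act_pMEK_by_pRaf1_pGab1",-0.5
"k_act_pPI3K_by_pERK",-0.5
"k_deact_pRaf1_by_pAkt",0
"k_act_pRaf1_by_pERK",-0.5
"k_act_pRaf1_by_aRas_pGab1",-0.5
"k_deact_pSOS_by_RSK_d",0
"HGF",0
"PDK1",-0.5
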