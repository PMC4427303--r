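id,label
M01,negative feedback ERK -| SOS1
M02,negative feedback p90RSK (RSK_d) -| SOS1
M03,positive feedback ERK -> Raf1 (RKIP release)
M04,positive feedback PIP3 -> Gab1 recruitment
M05,negative crosstalk Akt -| Raf1 (S259)
M06,crosstalk ERK -> PI3K
M07,Ras -> PI3K activation
M08,PDK1 -> MEK activation
M09,Gab1 -> MEK route via Rac and PAK (lumped)
M10,Gab1 -> Raf1 route via Rac and PAK (lumped)
M11,negative feedback ERK -| MEK (T292)
M12,PDK1 -> p90RSK (S227) activation
M13,p90RSK -> Ras route
M14,Met -> Rac activation (CrkL/DOCK180)
M15,Met -> Gab1 recruitment via Grb2 (indirect route)
M16,Rac -> PI3K positive feedback
M17,Met -> PAK activation
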