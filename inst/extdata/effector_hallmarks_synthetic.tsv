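effector_gene	hallmarks
VEGFA	Inducing angiogenesis
RAD51	Genome instability and mutation
RAD51C	Genome instability and mutation
BRCA1	Genome instability and mutation
PTCH1	Evading growth suppressors
E2F1	Resisting cell death;Sustaining proliferative signaling
RB1	Evading growth suppressors
RPS6KB1	Sustaining proliferative signaling
ELK1	Sustaining proliferative signaling
STAT5A	Sustaining proliferative signaling
CBLC	Sustaining proliferative signaling
ERBB3	Sustaining proliferative signaling
IGFBP3	Resisting cell death
BBC3	Resisting cell death
ILK	Activating invasion and metastasis
PTK2	Inducing angiogenesis
CDKN1A	Evading growth suppressors
FIGF	Inducing angiogenesis
CCND1	Sustaining proliferative signaling
KDR	Inducing angiogenesis
MAPK8	Sustaining proliferative signaling
PIM1	Resisting cell death
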