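effector_gene	functions
VEGFA	Angiogenesis
RAD51	DNA recombination
RAD51C	DNA recombination
BRCA1	DNA recombination
PTCH1	Tumor suppressor
E2F1	Apoptosis;Cell cycle
RB1	Cell cycle
RPS6KB1	Translation regulation
ELK1	Transcription;Transcription regulation
STAT5A	Transcription;Transcription regulation
CBLC	Ubl conjugation pathway
ERBB3	Cell differentiation
IGFBP3	Apoptosis
BBC3	Apoptosis
ILK	Cell growth;Metastasis
PTK2	Angiogenesis
CDKN1A	Cell cycle
FIGF	Angiogenesis
CCND1	Cell division;DNA damage
KDR	Angiogenesis
MAPK8	Biological rhythms
PIM1	Apoptosis;Cell cycle
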