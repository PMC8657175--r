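# Seventeen metastasis suppressor genes (MSG) with their functional category,
# as printed in the source survey (symbols verbatim, including ARGHDIB).
symbol	category
CD44	cell-cell adhesion
CD82	cell-cell adhesion
CDH11	cell-cell adhesion
CDH2	cell-cell adhesion
CDH1	cell-cell adhesion
GSN	cell-cell adhesion
AKAP12	scaffolding
MAP2K6	MAPK
MAP2K4	MAPK
MAP2K7	MAPK
MAPK14	MAPK
NME1	transcription
BRMS1	transcription
ARGHDIB	GTP-binding
DRG1	GTP-binding
RRM1	other
PEBP1	other
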