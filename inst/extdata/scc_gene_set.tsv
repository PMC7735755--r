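gene_id	direction
LAD1	up
HMGA2	up
S100A2	up
TMEM40	up
FGFBP1	up
IL1B	up
LPAR3	up
SFN	up
MMP14	up
VSNL1	up
FAT2	up
FERMT1	up
IRF6	up
RASSF6	up
PTHLH	up
XDH	up
TRIM7	up
CSTA	up
CYP27B1	up
FEZ1	up
GPX2	up
NIPAL4	up
PPP4R4	up
PBX1	down
RNASE7	up
SPOCK1	down
SERPINB13	up
COBL	down
COL17A1	up
CYP1B1	down
FABP5	up
FOSL1	up
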