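gene_id	score	proximal	enhancer	scc
DUSP6	14	yes	yes	no
FSCN1	8	yes	yes	no
RAB38	14	yes	yes	no
GINS3	8	yes	no	no
GSDME	13	yes	yes	no
GM2A	8	yes	yes	no
LAD1	13	yes	yes	yes
HMGA2	8	yes	yes	yes
S100A2	13	yes	yes	yes
HSPA4L	8	yes	yes	no
TMEM40	13	yes	yes	yes
JAG1	8	yes	yes	no
FGFBP1	12	yes	yes	yes
KCTD12	8	yes	no	no
HAS3	12	yes	no	no
KIAA0930	8	yes	yes	no
NECTIN1	12	yes	yes	no
KIF14	8	no	yes	no
TCOF1	12	yes	yes	no
KIRREL1	8	no	yes	no
DUSP7	11	yes	yes	no
LIG1	8	yes	yes	no
IL1B	11	no	yes	yes
LPAR3	8	yes	yes	yes
MREG	11	no	yes	no
LRRFIP2	8	no	yes	no
PA2G4	11	yes	no	no
MALT1	8	no	yes	no
RGS20	11	yes	no	no
MAST4	8	no	yes	no
SDC1	11	no	yes	no
MCM3	8	no	yes	no
SFN	11	yes	yes	yes
MMP14	8	yes	yes	yes
STK17A	11	yes	yes	no
MMRN2	8	yes	no	no
VSNL1	11	yes	yes	yes
NOM1	8	yes	no	no
ARHGAP25	10	yes	yes	no
NRCAM	8	yes	yes	no
CDCA4	10	yes	yes	no
NRG1	8	no	yes	no
DUSP11	10	yes	no	no
OAS3	8	yes	yes	no
FAT2	10	yes	no	yes
PPFIBP1	8	yes	yes	no
FERMT1	10	yes	yes	yes
PROCR	8	yes	no	no
IL4R	10	yes	yes	no
QSOX2	8	yes	yes	no
INPP1	10	yes	yes	no
RAD51C	8	yes	yes	no
IRF6	10	no	yes	yes
RASSF6	8	no	yes	yes
ITGA6	10	no	yes	no
RFX7	8	yes	no	no
KIZ	10	yes	no	no
SH3PXD2A	8	no	yes	no
MAPKBP1	10	no	yes	no
SLC1A5	8	yes	yes	no
MYO10	10	yes	yes	no
SLC2A9	8	yes	yes	no
MYO19	10	yes	yes	no
SLC37A2	8	yes	no	no
ORC1	10	no	yes	no
SMAD5	8	yes	no	no
PAK1	10	yes	no	no
SPATS2	8	no	yes	no
PTHLH	10	yes	yes	yes
SSRP1	8	no	yes	no
SMTN	10	yes	no	no
TGFB1	8	yes	yes	no
WDFY2	10	yes	no	no
TMEM237	8	yes	no	no
XDH	10	yes	yes	yes
TOMM34	8	yes	no	no
ARHGDIB	9	yes	yes	no
TRIM7	8	yes	yes	yes
AURKB	9	yes	no	no
TRIP13	8	yes	no	no
BTBD11	9	yes	no	no
TSPAN5	8	yes	no	no
C6orf106	9	yes	no	no
TSR1	8	no	yes	no
CARD10	9	yes	yes	no
TYMS	8	yes	yes	no
CHAF1A	9	no	yes	no
UCK2	8	yes	yes	no
CSTA	9	yes	no	yes
UTP4	8	no	yes	no
CYP27B1	9	yes	no	yes
YAP1	8	yes	no	no
FEZ1	9	yes	yes	yes
YES1	8	yes	yes	no
GNA15	9	yes	no	no
ZFP36L2	8	no	yes	no
GPX2	9	yes	no	yes
APH1B	-8	no	yes	no
GSTP1	9	yes	no	no
BIRC3	-8	yes	yes	no
HRAS	9	yes	yes	no
C9orf3	-8	yes	yes	no
IFI16	9	yes	yes	no
CHST3	-8	no	yes	no
KREMEN1	9	yes	yes	no
CPQ	-8	no	yes	no
LDLR	9	yes	no	no
DUSP8	-8	yes	no	no
MAPK6	9	yes	yes	no
EPCAM	-8	no	yes	no
MYO5A	9	no	yes	no
ERBB2	-8	no	yes	no
NCAPH2	9	yes	no	no
FBN1	-8	no	yes	no
NDE1	9	yes	yes	no
ITFG1	-8	yes	no	no
NDST1	9	yes	yes	no
LLGL2	-8	yes	yes	no
NIPAL4	9	yes	yes	yes
NCSTN	-8	no	yes	no
PPIF	9	no	yes	no
OPN3	-8	no	yes	no
PPP4R4	9	yes	no	yes
PBX1	-8	yes	yes	yes
PTTG1	9	yes	yes	no
PDXK	-8	no	yes	no
RAPGEF5	9	yes	yes	no
PLAC8	-8	yes	yes	no
RNASE7	9	yes	yes	yes
S100A4	-8	no	yes	no
RRP12	9	no	yes	no
SPOCK1	-8	no	yes	yes
SERPINB13	9	yes	no	yes
TNS3	-8	no	yes	no
SNCA	9	no	yes	no
ARL6IP5	-9	no	yes	no
STX6	9	yes	no	no
COBL	-9	no	yes	yes
AK4	8	no	yes	no
CUEDC1	-9	yes	yes	no
ARHGAP23	8	yes	yes	no
GSN	-9	yes	no	no
ASCC3	8	yes	yes	no
PDGFC	-9	yes	yes	no
BRCA1	8	yes	no	no
PGPEP1	-9	no	yes	no
BTBD10	8	yes	yes	no
PLXNB2	-9	yes	yes	no
CCNK	8	yes	no	no
PXDN	-9	no	yes	no
CCT4	8	yes	no	no
RALGPS1	-9	yes	yes	no
CD44	8	yes	yes	no
ROR1	-9	yes	no	no
CDC42SE1	8	yes	no	no
SLC16A5	-9	yes	yes	no
CDCA7	8	yes	no	no
TM4SF1	-9	yes	yes	no
COL17A1	8	yes	no	yes
ALDH3B1	-10	yes	yes	no
CRKL	8	yes	yes	no
CYP1B1	-10	no	yes	yes
DRAP1	8	yes	yes	no
HHAT	-10	yes	yes	no
EHD4	8	no	yes	no
MEGF8	-10	no	yes	no
ERCC6L	8	no	yes	no
PTGES	-10	yes	no	no
ESRP1	8	no	yes	no
PTTG1IP	-10	no	yes	no
FABP5	8	yes	no	yes
RPS27L	-10	yes	yes	no
FANCI	8	yes	yes	no
SECTM1	-10	yes	yes	no
FLOT2	8	yes	no	no
SLC22A5	-10	yes	no	no
FOSL1	8	yes	yes	yes
TNFSF15	-10	yes	yes	no
FRMD4B	8	yes	no	no
SRD5A3	-11	yes	no	no
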