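human_tf	n_human_degs	mouse_tf	n_mouse_degs	n_overlap	overlap_genes
MEF2C	213	Mef2c	369	15	DYNC1l1,ETV,EPHA5,MMP16,OLFM3,RIT2,ARHGAP25,CST3,TENM1,DOCK10,MPED2,S100A1,APOE,CD86,MITF
MEF2A	193	Mef2a	329	13	ATP1B2,DYNC1l1,ZFPM2,MMP16,PTCHD4,EPHA5,OLFM3,ARHGAP25,S100A1,SYN3,APOE,BLNK,CD86
NR3C1	150	Nr3c1	287	12	ZFPM2,EPHA3,GOLIM4,MMP16,OLFM3,DHRS3,RIT2,RAB27B,S100A1,SYN3,MITF,SLC9A3R1
JUND	146	Jund	200	10	CNTN4,ZFPM2,RAB27B,CNTN6,OLFM3,MARCKSL1,PCDH15,CST3,GRIK1,GRM3
ZEB1	88	Zeb1	263	10	KCND2,LUZP2,MMP16,PAM,ZFPM2,CDH10,PRKD1,FGF12,MPPED2,PCDH15
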