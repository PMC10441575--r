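signature_id	genes	annotation
S_13	TCL1A,VPREB3,CD22,EBF1,FCER2,STAG3,MS4A1,PARP15,CD79B,KHDRBS2,BANK1,FAM129C,CD79A,CXCR5,LINC00926,BACH2,AFF3,LY9,RALGPS2,SMIM14,FCRLA,CD37,SPIB,FCRL1,IRF8,CD19,CNR2,TNFRSF13B,ADAM28,COL19A1,PAX5,ARHGAP24,TCF4,BLK,PKIG,RIC3,IFT57,TNFRSF13C	B
S_14	CD1E,HLA-DQB2,CD1B,PKIB,CALCRL,CD1A,FCER1A,S100B,PLD4,CD1C,PPP1R14A,NAPSA,CD207	DC
S_10	APOE,CTSL,GPNMB,CD9,TREM2,CTSD,APOC1,ADAMDEC1,SPP1,MMP9,PLA2G7,LIPA,ACP5,NUPR1,FN1	Macrophage
S_5	CCL13,MS4A4A,SLC40A1,LYVE1,RNASE1,SIGLEC1,C1QA,STAB1,CXCL12,ABCA1,IGF1,GPR34,PLTP,C1QB,PMP22,A2M,LGMN,FOLR2,SLCO2B1,MRC1,DAB2,NRP1,LILRB5,C1QC,F13A1,PLAU	Macrophage
S_1	TPSAB1,HPGDS,ADCYAP1,CPA3,PLAT,GATA2,CTSG,HPGD,KIT,CLU,IL1RL1,KIAA1549,RSPH9,SYTL4,HDC,VWA5A,RGS13,TPSB2,LIPC,SLC18A2	Mast
S_8	LILRA5,SLC25A37,CFP,S100A12,CD300E,TIMP1,APOBEC3A,FCN1,TREM1,SLC11A1,VCAN,S100A9,S100A8,CDA,THBS1,FGR	Monocytes
S_4	GZMB,CD160,TXK,KIR2DL4,TMIGD2,CTSW,KRT86,KLRF1,SH2D1B,GNLY,PRF1,KLRD1,XCL2,CLIC3,XCL1,HOPX,MATK,PTGDR,KRT81,KLRC1	NK
S_9	SCT,RGS7,IRF4,VASH2,GPM6B,MAP1A,NME8,PTCRA,PTGDS,AEBP1,CLEC4C,SMPD3,TTC39A,PHEX,MMP23B,PLVAP,PLAC8,RASD1,LILRA4,PTPRS,DNASE1L3,LRRC26,SLC35F3,TPM2,KRT5,TSPAN13	pDC
S_12	IGLL5,FKBP11,ITM2C,XBP1,DPEP1,SEC11C,HSP90B1,TNFRSF17,SDC1,CAV1,SSR4,DERL3,MZB1,JSRP1,CERCAM	Plasma
S_11	FAS,TNFRSF25,PBX4,FAAH2,ICOS,CD28,CCR4,TMEM173,MAL,LTB,ARID5B,PBXIP1,TNIK,NPDC1,LEF1,FBLN7	T CD4
S_2	FASLG,CCL5,RAB27A,CD8B,CPNE7,CST7,OASL,GZMH,GZMA,CHST12,SAMD3,CLEC2B,CD8A,APOBEC3G,GZMM,SLA2,TNIP3,IFNG,TSEN54,CRTAM,C12orf75,LAG3,GZMK	T CD8
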