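original	medium
B	B
B naive	B
B memory	B
B intermediate	B
B cells	B
Plasma	Plasma
Plasmablast	Plasma
Plasma cells	Plasma
DC	DC
cDC	DC
cDC1	DC
cDC2	DC
mDC	DC
Myeloid DC	DC
pDC	pDC
Plasmacytoid DC	pDC
Monocytes	Monocytes
Mono	Monocytes
CD14 Mono	Monocytes
CD16 Mono	Monocytes
CD14+ Monocyte	Monocytes
FCGR3A+ Monocyte	Monocytes
Classical monocytes	Monocytes
Non-classical monocytes	Monocytes
NK	NK
NK cells	NK
NK_CD56bright	NK
CD56 bright NK	NK
CD4 T	CD4 T
CD4 Naive	CD4 T
CD4 TCM	CD4 T
CD4 TEM	CD4 T
CD4 CTL	CD4 T
Treg	CD4 T
naive CD4+ T	CD4 T
memory CD4+ T	CD4 T
regulatory CD4+ T	CD4 T
helper CD4+ T	CD4 T
CD4+ T cells	CD4 T
CD8 T	CD8 T
CD8 Naive	CD8 T
CD8 TCM	CD8 T
CD8 TEM	CD8 T
naive CD8+ T	CD8 T
cytotoxic CD8+ T	CD8 T
CD8+ T cells	CD8 T
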