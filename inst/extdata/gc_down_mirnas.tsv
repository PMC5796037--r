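dataset	mirna	log2fc
TCGA_STAD	miR-204-5p	-1.82
TCGA_STAD	miR-145-5p	-1.24
TCGA_STAD	miR-375	-0.86
TCGA_STAD	miR-642a-5p	-0.79
TCGA_STAD	miR-26a-5p	-0.68
TCGA_STAD	miR-30a-5p	-0.42
TCGA_STAD	miR-342-3p	-0.04
TCGA_STAD	miR-1-3p	-1.86
TCGA_STAD	miR-203a-3p	-1.03
GSE23739	miR-204-5p	-1.69
GSE23739	miR-375	-1.35
GSE23739	miR-145-5p	-1.35
GSE23739	miR-642a-5p	-1.31
GSE23739	miR-26a-5p	-0.88
GSE23739	miR-342-3p	-0.71
GSE23739	miR-30a-5p	-0.53
GSE30070	miR-375	-1.74
GSE30070	miR-204-5p	-1.35
GSE30070	miR-642a-5p	-0.75
GSE30070	miR-26a-5p	-0.47
GSE30070	miR-145-5p	-0.46
GSE30070	miR-342-3p	-0.14
GSE30070	miR-30a-5p	-0.09
GSE30070	miR-1-3p	-1.36
GSE30070	miR-203a-3p	-0.96
GSE33743	miR-1-3p	-2.49
GSE33743	miR-203a-3p	-1.14
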