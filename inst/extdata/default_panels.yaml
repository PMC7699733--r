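# Default marker panels. EV markers: frequently reported exosome proteins
# (tetraspanins, ESCRT and syntenin machinery). Non-EV markers: organelle
# proteins indicating cellular contamination (mitochondrial BCL2, Golgi
# GOLGA2, nuclear NUP98, endoplasmic-reticulum CANX). Population panels:
# editable marker lists for eight immune and two stromal populations; the
# shipped symbols are conventional protein markers, replace them with any
# curated signature.
ev_markers: [CD63, CD9, CD81, TSG101, PDCD6IP, SDCBP, FLOT1, ANXA2, HSPA8, GAPDH]
non_ev_markers: [BCL2, GOLGA2, NUP98, CANX]
populations:
  T cells: [CD3D, CD3E, CD3G, CD5, CD28]
  CD8 T cells: [CD8A, CD8B]
  Cytotoxic lymphocytes: [GZMA, GZMB, PRF1, KLRD1]
  B lineage: [CD19, MS4A1, CD79A, CD79B, IGKC]
  NK cells: [NCR1, NCAM1, KIR2DL3]
  Monocytic lineage: [CD14, CD163, CSF1R, ITGAM]
  Myeloid dendritic cells: [CD1A, CD1B, CLEC10A]
  Neutrophils: [FCGR3B, CEACAM8, ELANE, MPO]
  Endothelial cells: [PECAM1, VWF, CDH5]
  Fibroblasts: [COL1A1, COL3A1, DCN, FAP]
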