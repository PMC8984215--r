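# Major skin cell-type marker dictionary used for first-pass annotation.
Fibroblast: [LUM, PDGFRA, COL1A1, SFRP2, CCL19]
Perivascular: [RGS5, MYL9, NDUFA4L2]
Erythrocyte: [HBB, HBA2, HBA1]
Immune: [TPSB2, TPSAB1, HLA-DRA, FCER1G, CD74]
Melanocyte: [PMEL, MLANA]
EndothelialVascular: [CLDN5, PECAM1]
Keratinocyte: [DMKN, KRT1, KRT5]
MitochondrialLowQuality: [MTND2P8, MTND4P12, MTCO1P40, ADAM33, RN7SL2, MTRNR2L6]
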