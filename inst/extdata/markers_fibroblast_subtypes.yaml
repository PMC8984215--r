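# Dermal fibroblast subtype marker dictionary (A/B/C typology).
A1: [PI16, QPCT, SLPI, CCN5, CPE, CTHRC1, MFAP5, PCOLCE2, SCARA5, TSPAN8]
A2: [APCDD1, COL18A1, COMP, NKD2, F13A1, HSPB3, LEPR, TGFBI]
B1: [CXCL2, MYC, C7, SPSB1, ITM2A]
B2: [SOCS3, CCL19, CD74, RARRES2, CCDC146, IGFBP3, TNFSF13B]
C: [CRABP1, PLXDC1, RSPO4, ASPN, F2R, POSTN, TNN]
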