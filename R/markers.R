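#' Packaged marker dictionaries and artifact gene signatures
#'
#' Marker lists for the major skin cell types and for the dermal fibroblast
#' subtypes A1, A2, B1, B2 and C, plus the dissociation-stress
#' (immediate-early / heat-shock) and hypoxia (glycolysis / hypoxia-response)
#' gene programs used to flag artifact clusters. These are working defaults
#' shipped with the package; any dictionary in the same shape can be
#' substituted via [read_marker_dictionary()].
#'
#' @return [skin_cell_type_markers()] and [fibroblast_subtype_markers()]
#'   return a `marker_dict`; [stress_signature_genes()] and
#'   [hypoxia_signature_genes()] return character vectors.
#' @name packaged_markers
NULL

#' @rdname packaged_markers
#' @export
skin_cell_type_markers <- function() {
  marker_dictionary(list(
    Fibroblast = c("LUM", "PDGFRA", "COL1A1", "SFRP2", "CCL19"),
    Perivascular = c("RGS5", "MYL9", "NDUFA4L2"),
    Erythrocyte = c("HBB", "HBA2", "HBA1"),
    Immune = c("TPSB2", "TPSAB1", "HLA-DRA", "FCER1G", "CD74"),
    Melanocyte = c("PMEL", "MLANA"),
    EndothelialVascular = c("CLDN5", "PECAM1"),
    Keratinocyte = c("DMKN", "KRT1", "KRT5"),
    MitochondrialLowQuality = c("MTND2P8", "MTND4P12", "MTCO1P40",
                                "ADAM33", "RN7SL2", "MTRNR2L6")
  ))
}

#' @rdname packaged_markers
#' @export
fibroblast_subtype_markers <- function() {
  marker_dictionary(list(
    A1 = c("PI16", "QPCT", "SLPI", "CCN5", "CPE", "CTHRC1", "MFAP5",
           "PCOLCE2", "SCARA5", "TSPAN8"),
    A2 = c("APCDD1", "COL18A1", "COMP", "NKD2", "F13A1", "HSPB3",
           "LEPR", "TGFBI"),
    B1 = c("CXCL2", "MYC", "C7", "SPSB1", "ITM2A"),
    B2 = c("SOCS3", "CCL19", "CD74", "RARRES2", "CCDC146", "IGFBP3",
           "TNFSF13B"),
    C = c("CRABP1", "PLXDC1", "RSPO4", "ASPN", "F2R", "POSTN", "TNN")
  ))
}

#' @rdname packaged_markers
#' @export
stress_signature_genes <- function() {
  c("ATF3", "BTG2", "FOS", "FOSB", "GADD45B", "HSPA1A", "HSPA1B",
    "IER2", "IER3", "JUN", "JUNB", "NFKBIA", "NR4A1", "NR4A2",
    "PPP1R15A", "RHOB")
}

#' @rdname packaged_markers
#' @export
hypoxia_signature_genes <- function() {
  c("ALDOC", "ENO2", "GAPDH", "PGK1", "PDK1", "PFKFB4", "PYGL",
    "BNIP3", "BNIP3L", "ANGPTL4", "LOX", "HILPDA")
}

#' Packaged stress and hypoxia signature definitions
#'
#' Ready-to-use [signature_definition()] objects: the dissociation-stress
#' program with classification threshold 0.55 and fallback label
#' `"Non-stress"`, and the hypoxia program with threshold 0.5 and fallback
#' `"Normal"`. A cluster whose percentile-aggregated signature score falls
#' strictly below the threshold receives the fallback label.
#'
#' @return A `signature_def` object.
#' @name packaged_signatures
NULL

#' @rdname packaged_signatures
#' @export
stress_signature <- function() {
  signature_definition(name = "Stress", genes = stress_signature_genes(),
                       threshold = 0.55, fallback_label = "Non-stress")
}

#' @rdname packaged_signatures
#' @export
hypoxia_signature <- function() {
  signature_definition(name = "Hypoxia", genes = hypoxia_signature_genes(),
                       threshold = 0.5, fallback_label = "Normal")
}
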