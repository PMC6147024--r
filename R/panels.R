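#' Default epigenetic-regulator gene panel
#'
#' The DNA methylation machinery genes examined against global methylation
#' and anchor-gene expression: the maintenance and de novo
#' methyltransferases, their UHRF cofactors, the active demethylation
#' (TET) enzymes and the APOBEC3 deaminases.
#'
#' @format Character vector of gene symbols.
#' @export
epigenetic_regulators <- c(
  "DNMT1", "DNMT3A", "DNMT3B", "UHRF1", "UHRF2",
  "TET1", "TET2", "TET3", "APOBEC3F", "APOBEC3G"
)

#' Default viral-mimicry / immune gene panel
#'
#' Thirty type-I-interferon-stimulated, viral-mimicry and immune genes
#' used for the panel heatmaps. The core members (IFI44, IFI27, OASL,
#' IL29, IFNB1, IRF7, DDX58, IRF1, TLR3) are the explicitly highlighted
#' viral-mimicry genes; the remainder are canonical interferon-stimulated
#' genes completing a representative 30-gene panel.
#'
#' @format Character vector of gene symbols.
#' @export
viral_mimicry_panel <- c(
  "IFI44", "IFI27", "OASL", "IL29", "IFNB1", "IRF7", "DDX58", "IRF1", "TLR3",
  "IFI6", "IFI16", "IFI35", "IFIT1", "IFIT2", "IFIT3", "IFITM1", "ISG15",
  "MX1", "MX2", "OAS1", "OAS2", "OAS3", "IRF9", "STAT1", "STAT2", "IFIH1",
  "IL15", "CXCL10", "TNFSF10", "B2M"
)
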