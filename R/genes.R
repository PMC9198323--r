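## Gene universes used by the synthetic generators and as pipeline defaults.
## The human panel is a synthetic stand-in for a targeted fibrosis panel:
## 82 genes partitioned into cell-type categories (cardiomyocyte 24,
## fibroblast/pericyte 20, both 15, other 23) plus 5 reference genes.

#' Reference (housekeeping) genes of the expression panel
#'
#' The five invariant genes used for per-sample normalization of panel
#' counts: GAPDH, GUSB, PGK1, POLR2A and RPLP0.
#'
#' @return Character vector of five gene symbols.
#' @export
panelReferenceGenes <- function() {
    c("GAPDH", "GUSB", "PGK1", "POLR2A", "RPLP0")
}

#' The 12-gene fibrosis signature
#'
#' The compact heart-failure fibrosis signature: seven collagens, fibrillin-1,
#' TIMP3, TGFB1, CCL2 and ACE2. All genes except ACE2 are expected to be
#' elevated in the severe-fibrosis patient subcluster; ACE2 runs in the
#' opposite direction.
#'
#' @return Character vector of 12 human gene symbols.
#' @export
fibrosisSignatureGenes <- function() {
    c("COL1A1", "COL1A2", "COL3A1", "COL6A1", "COL12A1", "COL14A1",
      "COL15A1", "FBN1", "TIMP3", "TGFB1", "CCL2", "ACE2")
}

## Panel gene categories (synthetic composition; sizes 24/20/15/23).
.panel_cm_genes <- c(
    "MYH7", "MYH6", "TNNT2", "TNNI3", "MYL2", "MYL3", "ACTC1", "NPPA",
    "NPPB", "TTN", "MYBPC3", "RYR2", "ATP2A2", "PLN", "CASQ2", "ACTN2",
    "DES", "TCAP", "CSRP3", "LDB3", "MYOZ2", "TNNC1", "TPM1", "NEBL")

.panel_fb_genes <- c(
    fibrosisSignatureGenes(),
    "POSTN", "FAP", "PDGFRA", "PDGFRB", "LUM", "DCN", "FMOD", "LOX")

.panel_both_genes <- c(
    "FN1", "SPARC", "TNC", "THBS1", "THBS4", "CCN2", "MMP2", "TIMP1",
    "TGFB2", "TGFB3", "SMAD3", "SMAD7", "ITGB1", "ILK", "LTBP2")

.panel_other_genes <- c(
    "PTPRC", "CD68", "CD163", "IL6", "IL1B", "TNF", "CCL5", "CXCL9",
    "PECAM1", "VWF", "CDH5", "KDR", "TEK", "NOS3", "ACTA2", "MYH11",
    "CNN1", "TAGLN", "CD34", "CD14", "ITGAM", "EMCN", "LYVE1")

#' Panel gene table
#'
#' The 82-gene fibrosis panel bundled with the package, with each gene's
#' cell-type category (the partition used by the synthetic cell-type
#' reference: 24 cardiomyocyte, 20 fibroblast/pericyte, 15 both, 23 other).
#' The gene list is synthetic: plausible human symbols standing in for a
#' proprietary panel whose identity is not public, anchored on the 12-gene
#' fibrosis signature.
#'
#' @return A data.frame with columns \code{gene} and \code{category}.
#' @export
panelGeneTable <- function() {
    data.frame(
        gene = c(.panel_cm_genes, .panel_fb_genes, .panel_both_genes,
                 .panel_other_genes),
        category = rep(c("cardiomyocyte", "fibroblast_pericyte", "both",
                         "other"),
                       times = c(length(.panel_cm_genes),
                                 length(.panel_fb_genes),
                                 length(.panel_both_genes),
                                 length(.panel_other_genes))),
        stringsAsFactors = FALSE)
}

#' Human/mouse symbol map for the signature genes
#'
#' Cross-species matching of the human panel signature to mouse single-cell
#' data uses an explicit symbol map (upper-case human symbol, title-case
#' mouse symbol).
#'
#' @param genes Human gene symbols to map; defaults to the 12-gene signature.
#' @return A data.frame with columns \code{human} and \code{mouse}.
#' @export
humanMouseMap <- function(genes = fibrosisSignatureGenes()) {
    mouse <- paste0(substr(genes, 1, 1),
                    tolower(substr(genes, 2, nchar(genes))))
    data.frame(human = genes, mouse = mouse, stringsAsFactors = FALSE)
}

#' Default proliferation gene set (mouse)
#'
#' A 17-gene equal-weight proliferation score set including Ccnd1, Ccnd2,
#' Mki67 and Pcna; the remaining members are canonical cell-cycle effectors.
#'
#' @return Character vector of 17 mouse gene symbols.
#' @export
proliferationGenes <- function() {
    c("Ccnd1", "Ccnd2", "Mki67", "Pcna", "Top2a", "Ccnb1", "Ccna2",
      "Cdk1", "Birc5", "Aurka", "Plk1", "Bub1", "Cenpa", "Mcm2",
      "Mcm5", "Tyms", "Rrm2")
}

#' Cell-cycle phase gene sets (mouse)
#'
#' S-phase and G2/M gene sets used for per-cell phase calling.
#'
#' @return Named list with elements \code{S} and \code{G2M}.
#' @export
cellCycleGenes <- function() {
    list(S = c("Pcna", "Mcm2", "Mcm5", "Tyms", "Rrm2", "Fen1", "Gins2",
               "Cdc6"),
         G2M = c("Mki67", "Top2a", "Ccnb1", "Ccna2", "Cdk1", "Birc5",
                 "Aurka", "Plk1", "Bub1", "Cenpa", "Ube2c"))
}

## Population structure of the synthetic culture dataset.
.culture_populations <- c("EC", "MP1", "MP2", "FB1", "FB2", "FB3", "FB4",
                          "FB5", "FB6")

## Unique (population-restricted) marker genes of the culture generator.
.culture_unique_markers <- list(
    EC  = c("Emcn", "Pecam1", "Cdh5", "Kdr"),
    MP1 = c("Il1b", "Ccr2", "Cxcl2", "Tlr2"),
    MP2 = c("Cd163", "Mrc1", "Stab1", "Gas6"),
    FB1 = c("Cald1", "Gsn", "Dpt", "Pi16"),
    FB2 = c("Tpm2", "Myh10", "Tagln2", "Thy1"),
    FB3 = c("S100a4", "Thbs4", "Igfbp3", "Clu"),
    FB4 = c("Efhd2", "Cd44", "Tnc", "Runx1"),
    FB5 = c("Ltbp2", "Comp", "Sfrp2", "Ccn4"),
    FB6 = c("Malat1", "Eln", "Mgp", "Cilp"))

#' Unique marker genes of the synthetic culture populations
#'
#' @return Named list (one character vector per population EC, MP1, MP2,
#'   FB1..FB6) of the markers planted as population-restricted by
#'   \code{\link{generateCultureData}}.
#' @export
cultureMarkerGenes <- function() .culture_unique_markers
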