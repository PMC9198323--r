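## Synthetic cell-type reference constructor: builds a per-cell-type mean
## expression matrix whose gene-category assignment (under the default
## predominance rule) recovers a supplied partition exactly in the
## noiseless case.

#' Ground-truth panel gene partition
#'
#' The bundled panel's gene -> category map (24 cardiomyocyte, 20
#' fibroblast/pericyte, 15 both, 23 other).
#'
#' @return Named character vector over the 82 panel genes.
#' @export
panelPartition <- function() {
    tab <- panelGeneTable()
    stats::setNames(tab$category, tab$gene)
}

#' Generate a synthetic cell-type reference
#'
#' For each gene, per-cell-type mean expression is constructed so that the
#' pooled-group expression-mass fractions are (0.8, 0.1, 0.1) for a
#' cardiomyocyte gene, (0.1, 0.8, 0.1) for a fibroblast/pericyte gene,
#' (0.42, 0.42, 0.16) for a "both" gene and (0.15, 0.15, 0.7) for "other"
#' (each group's total split evenly over its member cell types) — all on
#' the correct side of the default rule thresholds, so
#' \code{\link{assignGeneCategories}} recovers the partition exactly when
#' \code{noise = 0}.
#'
#' @param partition named character vector, gene -> category in
#'   \{cardiomyocyte, fibroblast_pericyte, both, other\}.
#' @param noise lognormal s.d. of multiplicative noise on the reference
#'   values (0 = noiseless).
#' @param scale overall expression scale.
#' @param seed RNG seed (used only when \code{noise > 0}).
#' @return A \linkS4class{CellTypeReference} with cell types cardiomyocyte,
#'   fibroblast, pericyte, endothelial, macrophage, lymphocyte, adipocyte.
#' @export
generateCellTypeReference <- function(partition = panelPartition(),
                                      noise = 0, scale = 100, seed = 0) {
    cats <- c("cardiomyocyte", "fibroblast_pericyte", "both", "other")
    if (!all(partition %in% cats))
        stop("unknown category label: ",
             paste(setdiff(unique(partition), cats), collapse = ", "))
    types <- c("cardiomyocyte", "fibroblast", "pericyte", "endothelial",
               "macrophage", "lymphocyte", "adipocyte")
    groups <- stats::setNames(
        c("cardiomyocyte", "fibroblast_pericyte", "fibroblast_pericyte",
          "other", "other", "other", "other"), types)
    ## target pooled-group fractions per category (CM, FB, other)
    target <- rbind(cardiomyocyte       = c(0.80, 0.10, 0.10),
                    fibroblast_pericyte = c(0.10, 0.80, 0.10),
                    both                = c(0.42, 0.42, 0.16),
                    other               = c(0.15, 0.15, 0.70))
    means <- matrix(0, length(partition), length(types),
                    dimnames = list(names(partition), types))
    for (g in seq_along(partition)) {
        tg <- target[partition[g], ]
        ## each group's expression mass, split evenly over its cell types
        means[g, ] <- scale *
            c(tg[1], tg[2] / 2, tg[2] / 2,
              tg[3] / 4, tg[3] / 4, tg[3] / 4, tg[3] / 4)
    }
    if (noise > 0) {
        set.seed(seed)
        means <- means * matrix(stats::rlnorm(length(means), 0, noise),
                                nrow(means), ncol(means))
    }
    CellTypeReference(means, groups)
}
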