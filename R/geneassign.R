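## Assigning panel genes to cell-type categories from a reference
## mean-expression matrix, via pooled-group specificity fractions.

#' Assign genes to cell-type categories
#'
#' Per gene, cell types are pooled into three groups (cardiomyocyte;
#' fibroblast + pericyte; all others) and specificity fractions
#' s_g = group total / sum over all cell types are computed (the share of
#' the gene's expression mass attributable to each group, so a gene
#' uniform across many cell types is never called group-specific). The
#' category is
#' "cardiomyocyte" if s_CM >= theta_dom and s_FB < theta_both (and
#' symmetrically "fibroblast_pericyte"), "both" if both s_CM and s_FB are >=
#' theta_both and neither dominant rule fired, otherwise "other". All-zero
#' genes are assigned "other" and flagged.
#'
#' @param ref A \linkS4class{CellTypeReference}.
#' @param genes genes to assign (default: all reference genes).
#' @param theta_dom dominance threshold (default 0.5).
#' @param theta_both shared-expression threshold (default 0.3); must be <=
#'   theta_dom.
#' @return data.frame with \code{gene}, \code{category}, the specificity
#'   fractions \code{s_cm}, \code{s_fb}, \code{s_other}, and
#'   \code{all_zero}.
#' @export
assignGeneCategories <- function(ref, genes = rownames(categoryMeans(ref)),
                                 theta_dom = 0.5, theta_both = 0.3) {
    stopifnot(is(ref, "CellTypeReference"), theta_both <= theta_dom)
    means <- categoryMeans(ref)
    missing <- setdiff(genes, rownames(means))
    if (length(missing))
        stop("genes missing from reference: ",
             paste(missing, collapse = ", "))
    means <- means[genes, , drop = FALSE]
    grp <- typeGroups(ref)
    gm <- vapply(c("cardiomyocyte", "fibroblast_pericyte", "other"),
                 function(g) {
                     cols <- names(grp)[grp == g]
                     rowSums(means[, cols, drop = FALSE])
                 }, numeric(length(genes)))
    if (length(genes) == 1L)
        gm <- matrix(gm, 1, dimnames = list(genes, names(gm)))
    tot <- rowSums(gm)
    all_zero <- tot == 0
    s <- gm / ifelse(tot == 0, 1, tot)
    category <- ifelse(
        s[, 1] >= theta_dom & s[, 2] < theta_both, "cardiomyocyte",
        ifelse(s[, 2] >= theta_dom & s[, 1] < theta_both,
               "fibroblast_pericyte",
               ifelse(s[, 1] >= theta_both & s[, 2] >= theta_both, "both",
                      "other")))
    category[all_zero] <- "other"
    data.frame(gene = genes, category = category,
               s_cm = s[, 1], s_fb = s[, 2], s_other = s[, 3],
               all_zero = all_zero, row.names = genes)
}

#' Category counts of a gene assignment
#'
#' @param assign data.frame from \code{\link{assignGeneCategories}}.
#' @return Named integer vector over the four categories (zero-filled).
#' @export
categoryCounts <- function(assign) {
    cats <- c("cardiomyocyte", "fibroblast_pericyte", "both", "other")
    tab <- table(factor(assign$category, levels = cats))
    stats::setNames(as.integer(tab), cats)
}
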