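## Staging of bulk time courses with subpopulation marker sets, plus the
## shared multiple-testing and overlap-test primitives.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values: q_(i) = min over j >= i of m * p_(j) / j, clipped
#' at 1, returned in input order.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' One-way ANOVA differential expression across stages
#'
#' Per gene, a one-way F-test across the stage groups on log1p expression,
#' with BH q-values; the DE set is \{q < alpha\}. Genes with zero
#' within-group variance and equal means get p = 1 and are flagged.
#'
#' @param bulk A \linkS4class{BulkTimecourse}.
#' @param alpha q-value cutoff for the DE set.
#' @return List with \code{table} (F, p, q per gene) and \code{de_genes}.
#' @export
anovaDE <- function(bulk, alpha = 0.05) {
    stopifnot(is(bulk, "BulkTimecourse"))
    stage <- stageLabels(bulk)
    if (any(table(stage) < 2))
        stop("each stage needs >= 2 replicates")
    x <- log1p(assay(bulk, "counts"))
    res <- rowAnovaF(x, stage)
    res$q <- bhAdjust(res$p)
    res$flat <- is.nan(res$F) | is.infinite(res$F)
    list(table = res, de_genes = rownames(res)[!is.na(res$q) &
                                               res$q < alpha])
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability P(X >= k) of observing at least the seen overlap
#' between a marker set and a DE set drawn from a shared gene universe.
#'
#' @param marker_set,de_set gene id vectors (subsets of universe).
#' @param universe gene universe.
#' @return List of class \code{OverlapTest}: N, K, n, k, expected overlap
#'   n*K/N, and the upper-tail p.
#' @export
hypergeomOverlap <- function(marker_set, de_set, universe) {
    marker_set <- unique(marker_set); de_set <- unique(de_set)
    if (!all(marker_set %in% universe) || !all(de_set %in% universe))
        stop("marker and DE sets must be subsets of the universe")
    N <- length(unique(universe))
    K <- length(de_set)
    n <- length(marker_set)
    if (n > N) stop("marker set larger than universe")
    k <- length(intersect(marker_set, de_set))
    p <- if (k == 0) 1
         else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    structure(list(N = N, K = K, n = n, k = k,
                   expected = n * K / N, p = min(p, 1)),
              class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
    cat(sprintf(
        "Hypergeometric overlap: %d of %d markers in a %d-gene DE set\n",
        x$k, x$n, x$K))
    cat(sprintf("  universe %d, expected overlap %.2f, P(X >= k) = %.3g\n",
                x$N, x$expected, x$p))
    invisible(x)
}

#' Stage separation of a marker-set PCA
#'
#' z-scores the selected genes across samples, computes a PCA, and scores
#' how well stages separate as the mean silhouette width of the stage
#' labels in the first n_pc components. Per-PC variance percentages are
#' reported for axis labelling.
#'
#' @param bulk A \linkS4class{BulkTimecourse}.
#' @param gene_set genes to use (>= 3 present in the data); NULL = all.
#' @param n_pc components used for the silhouette (default 2).
#' @return List with \code{coords}, \code{silhouette}, \code{var_pct}.
#' @export
pcaStageSeparation <- function(bulk, gene_set = NULL, n_pc = 2) {
    stage <- stageLabels(bulk)
    if (length(unique(stage)) < 2) stop("need >= 2 stages")
    x <- log1p(assay(bulk, "counts"))
    if (!is.null(gene_set)) {
        gene_set <- intersect(gene_set, rownames(x))
        if (length(gene_set) < 3)
            stop("gene_set must overlap the data in >= 3 genes")
        x <- x[gene_set, , drop = FALSE]
    }
    z <- rowZscore(x)
    z <- z[apply(z, 1, function(r) any(r != 0)), , drop = FALSE]
    pc <- stats::prcomp(t(z), center = FALSE)
    n_pc <- min(n_pc, ncol(pc$x))
    coords <- pc$x[, seq_len(n_pc), drop = FALSE]
    sil <- cluster::silhouette(as.integer(factor(stage)),
                               stats::dist(coords))
    list(coords = coords,
         silhouette = mean(sil[, "sil_width"]),
         var_pct = 100 * pc$sdev^2 / sum(pc$sdev^2))
}

#' Stage x marker-set score heatmap
#'
#' Per gene, z-score across samples; scores are averaged within each marker
#' set and then within each stage. The per-set peak stage is the argmax row.
#' Sets with no genes in the data are skipped with a message.
#'
#' @param bulk A \linkS4class{BulkTimecourse}.
#' @param marker_sets named list of gene sets.
#' @return List with \code{matrix} (stages x sets) and \code{peak_stage}
#'   (named character).
#' @export
stageScoreHeatmap <- function(bulk, marker_sets) {
    stage <- stageLabels(bulk)
    z <- rowZscore(log1p(assay(bulk, "counts")))
    cols <- list()
    for (nm in names(marker_sets)) {
        gs <- intersect(marker_sets[[nm]], rownames(z))
        if (!length(gs)) {
            message("marker set ", nm, " absent from data; skipped")
            next
        }
        per_sample <- colMeans(z[gs, , drop = FALSE])
        cols[[nm]] <- vapply(split(per_sample, stage), mean, numeric(1))
    }
    if (!length(cols)) stop("no marker set overlaps the data")
    mat <- do.call(cbind, cols)
    mat <- mat[levels(stage), , drop = FALSE]
    list(matrix = mat,
         peak_stage = apply(mat, 2, function(v) rownames(mat)[which.max(v)]))
}
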