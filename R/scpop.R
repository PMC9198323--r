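## Single-cell stage: QC, doublet scoring, normalization, clustering,
## markers, cell typing, fibroblast state, cell cycle, proliferation,
## population fractions.

#' Filter genes by total spliced and unspliced counts
#'
#' Keeps genes whose total spliced count and total unspliced count are both
#' at least \code{min_count}.
#'
#' @param data An \linkS4class{SCCultureData}.
#' @param min_count minimum per-layer total (default 20).
#' @return The filtered object.
#' @export
qcFilterGenes <- function(data, min_count = 20) {
    stopifnot(ncol(data) > 0)
    keep <- rowSums(spliced(data)) >= min_count &
        rowSums(unspliced(data)) >= min_count
    if (!any(keep)) stop("QC removed all genes")
    data[keep, ]
}

## internal: median-total scaling + log1p of a counts matrix (genes x cells)
.normalizeCounts <- function(counts) {
    totals <- colSums(counts)
    target <- stats::median(totals)
    log1p(sweep(counts, 2, target / totals, `*`))
}

## internal: PCA scores of cells (rows) on the top variable genes
.cellPCA <- function(logc, n_hvg = 100, n_pcs = 30) {
    v <- matrixRowVars(logc)
    hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(logc)))]
    x <- t(logc[hvg, , drop = FALSE])
    x <- sweep(x, 2, colMeans(x))
    n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
    if (ncol(x) > 200) {
        pc <- irlba::prcomp_irlba(x, n = n_pcs, center = FALSE)
        scores <- pc$x
    } else {
        scores <- stats::prcomp(x, center = FALSE)$x[, seq_len(n_pcs),
                                                     drop = FALSE]
    }
    rownames(scores) <- rownames(x)
    scores
}

matrixRowVars <- function(x) {
    mu <- rowMeans(x)
    rowSums((x - mu)^2) / (ncol(x) - 1)
}

#' Score cells for doublet similarity
#'
#' Simulates synthetic doublets as sums of the spliced counts of random cell
#' pairs, co-embeds observed and synthetic cells by PCA, and scores each
#' observed cell by the fraction of synthetic doublets among its k nearest
#' neighbours, rescaled by the simulation ratio. Cells above the
#' \code{threshold} quantile of scores are flagged for removal.
#'
#' @param data An \linkS4class{SCCultureData}.
#' @param k neighbours (default 30).
#' @param sim_ratio synthetic doublets per observed cell (default 1).
#' @param threshold flag quantile (default 0.99).
#' @param n_hvg,n_pcs embedding parameters.
#' @param seed RNG seed.
#' @return List with \code{score} (per cell), \code{flagged} (logical
#'   removal mask) and \code{threshold_value}.
#' @export
doubletScore <- function(data, k = 30, sim_ratio = 1.0, threshold = 0.99,
                         n_hvg = 100, n_pcs = 30, seed = 0) {
    n <- ncol(data)
    if (2 * k >= n) stop("k too large for the number of cells")
    m <- ceiling(sim_ratio * n)
    set.seed(seed)
    i1 <- sample(n, m, TRUE)
    i2 <- sample(n, m, TRUE)
    fix <- i1 == i2
    i2[fix] <- (i2[fix] %% n) + 1L
    counts <- spliced(data)
    sim <- counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]
    colnames(sim) <- sprintf("sim%06d", seq_len(m))
    logc <- .normalizeCounts(cbind(counts, sim))
    scores <- .cellPCA(logc, n_hvg, n_pcs)
    nn <- knnIndices(scores, k)[seq_len(n), , drop = FALSE]
    frac_sim <- rowMeans(nn > n)
    score <- frac_sim / sim_ratio
    names(score) <- colnames(data)
    thr <- stats::quantile(score, threshold)
    list(score = score, flagged = score > thr, threshold_value = thr)
}

#' Normalize, embed and graph the cells
#'
#' Scales each cell's spliced counts to the median total and log1p
#' transforms them (\code{logcounts} assay), computes a PCA on the top
#' variable genes (optionally per-batch mean-centred), builds a kNN graph
#' in PC space, and stores the first two PCs as the default 2-D embedding.
#' Cells with zero totals are removed with a message.
#'
#' @param data An \linkS4class{SCCultureData} (after QC).
#' @param n_hvg number of highly variable genes for the PCA.
#' @param n_pcs number of principal components.
#' @param k kNN graph neighbours.
#' @param batch_correct per-batch mean-centring of the PC scores.
#' @return The object with \code{logcounts}, \code{reducedDims} "PCA" and
#'   "EMB", and the kNN index matrix in \code{metadata()$knn}.
#' @export
preprocessCells <- function(data, n_hvg = 100, n_pcs = 30, k = 20,
                            batch_correct = FALSE) {
    totals <- colSums(spliced(data))
    if (any(totals == 0)) {
        message("removed ", sum(totals == 0), " cell(s) with zero totals")
        data <- data[, totals > 0]
    }
    assay(data, "logcounts") <- .normalizeCounts(spliced(data))
    scores <- .cellPCA(assay(data, "logcounts"), n_hvg, n_pcs)
    if (batch_correct) {
        for (b in unique(colData(data)$batch)) {
            idx <- colData(data)$batch == b
            scores[idx, ] <- sweep(scores[idx, , drop = FALSE], 2,
                                   colMeans(scores[idx, , drop = FALSE]))
        }
    }
    SingleCellExperiment::reducedDim(data, "PCA") <- scores
    emb <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
    if (ncol(emb) < 2) emb <- cbind(emb, 0)
    SingleCellExperiment::reducedDim(data, "EMB") <- emb
    metadata(data)$knn <- knnIndices(scores, k)
    data
}

#' Louvain clustering of the kNN graph
#'
#' Community detection on the undirected kNN graph at the given resolution;
#' deterministic given the seed.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed.
#' @return Factor of cluster labels (also stored in
#'   \code{colData()$cluster} of the returned object when assigned back).
#' @export
clusterCells <- function(data, resolution = 1, seed = 0) {
    nn <- metadata(data)$knn
    if (is.null(nn)) stop("no kNN graph; run preprocessCells() first")
    edges <- cbind(rep(seq_len(nrow(nn)), ncol(nn)), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                      directed = FALSE))
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    factor(igraph::membership(cl))
}

#' Resolution scan for Louvain clustering
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param resolutions resolutions to scan.
#' @param truth optional ground-truth labels; when given, the adjusted Rand
#'   index per resolution is reported.
#' @param seed RNG seed.
#' @return data.frame with \code{resolution}, \code{n_clusters} and
#'   (optionally) \code{ari}.
#' @export
scanResolutions <- function(data, resolutions = c(0.25, 0.5, 1, 1.5, 2),
                            truth = NULL, seed = 0) {
    rows <- lapply(resolutions, function(r) {
        cl <- clusterCells(data, resolution = r, seed = seed)
        out <- data.frame(resolution = r, n_clusters = nlevels(cl))
        if (!is.null(truth))
            out$ari <- mclust::adjustedRandIndex(cl, truth)
        out
    })
    do.call(rbind, rows)
}

#' Majority-vote mapping of clusters to ground-truth populations
#'
#' @param clusters cluster labels.
#' @param truth ground-truth labels (same length).
#' @return Named character vector: for each cluster level, the truth label
#'   holding the majority of its cells.
#' @export
mapClustersToTruth <- function(clusters, truth) {
    vapply(split(as.character(truth), clusters),
           function(x) names(which.max(table(x))), character(1))
}

#' Cluster marker genes by t-test
#'
#' Welch t-test of each gene, cluster vs all other cells, on the normalized
#' layer; per cluster the top_n genes by t statistic, with BH q-values
#' computed across genes within the cluster.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param labels per-cell cluster labels.
#' @param top_n markers per cluster (default 10).
#' @return data.frame with \code{cluster}, \code{rank}, \code{gene},
#'   \code{t}, \code{p}, \code{q}.
#' @export
clusterMarkers <- function(data, labels, top_n = 10) {
    logc <- assay(data, "logcounts")
    labels <- factor(labels)
    if (any(table(labels) < 3)) stop("each cluster needs >= 3 cells")
    res <- lapply(levels(labels), function(cl) {
        tt <- rowWelchT(logc, labels == cl, labels != cl)
        tt <- tt[!rownames(tt) %in% attr(tt, "skipped"), ]
        tt$q <- bhAdjust(tt$p)
        tt <- tt[order(-tt$t), ][seq_len(min(top_n, nrow(tt))), ]
        data.frame(cluster = cl, rank = seq_len(nrow(tt)),
                   gene = rownames(tt), t = tt$t, p = tt$p, q = tt$q)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Marker-rule cell typing
#'
#' Per-cell z-scores of the normalized marker expression; rule order:
#' Emcn-high is endothelial, else Lyz2-high is macrophage, else fibroblast.
#' Double-positive flags record Acta2-high macrophages and Lyz2-high
#' fibroblasts; with a single threshold Lyz2-high cells are called
#' macrophage by precedence, so the fibroblast flag uses its own (lower)
#' threshold.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param markers named list with \code{endothelial}, \code{macrophage},
#'   \code{fibroblast} marker gene(s); the endothelial call averages several
#'   markers because a single rare-population gene cannot beat count noise.
#' @param z_high z-score call threshold (default 1).
#' @param z_flag z-score threshold for the double-positive flags (default
#'   0.5).
#' @return data.frame with \code{label} and flags \code{acta2_positive},
#'   \code{lyz2_positive}.
#' @export
classifyCellTypes <- function(data,
                              markers = list(endothelial = c("Emcn",
                                                             "Pecam1",
                                                             "Cdh5"),
                                             macrophage = "Lyz2",
                                             fibroblast = c("Acta2",
                                                            "Col1a1")),
                              z_high = 1, z_flag = 0.5) {
    logc <- assay(data, "logcounts")
    need <- unlist(markers)
    missing <- setdiff(need, rownames(logc))
    if (length(missing))
        stop("marker gene(s) missing: ", paste(missing, collapse = ", "))
    zs <- function(gs) {
        z <- rowZscore(logc[gs, , drop = FALSE])
        colMeans(z)
    }
    z_ec <- zs(markers$endothelial)
    z_mp <- zs(markers$macrophage)
    z_fb <- zs(markers$fibroblast)
    z_acta2 <- if ("Acta2" %in% rownames(logc)) zs("Acta2") else z_fb
    label <- ifelse(z_ec > z_high, "endothelial",
                    ifelse(z_mp > z_high, "macrophage", "fibroblast"))
    data.frame(label = label,
               acta2_positive = label == "macrophage" & z_acta2 > z_high,
               lyz2_positive = label == "fibroblast" & z_mp > z_flag,
               row.names = colnames(data))
}

#' Matrix-producing vs contractile fibroblast state
#'
#' Among fibroblasts, compares the mean z-score of the collagen set against
#' the mean z-score of the contractile (Acta2/Tpm2) set; the larger wins and
#' exact ties go to the contractile state. z-scores are computed across the
#' fibroblast cells only.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param fb_cells logical mask or indices of fibroblast cells.
#' @param col_set,acta_set marker gene sets of the two states.
#' @return List with \code{state} (per fibroblast) and \code{fractions}.
#' @export
classifyFbState <- function(data, fb_cells,
                            col_set = c("Col1a1", "Col1a2", "Col3a1"),
                            acta_set = c("Acta2", "Tpm2")) {
    sub <- data[, fb_cells]
    if (ncol(sub) == 0) stop("no fibroblast cells")
    logc <- assay(sub, "logcounts")
    col_score <- colMeans(rowZscore(logc[col_set, , drop = FALSE]))
    acta_score <- colMeans(rowZscore(logc[acta_set, , drop = FALSE]))
    state <- ifelse(col_score > acta_score, "matrix_producing",
                    "contractile")
    names(state) <- colnames(sub)
    frac <- c(matrix_producing = mean(state == "matrix_producing"),
              contractile = mean(state == "contractile"))
    list(state = state, fractions = frac)
}

#' Cell-cycle phase calls
#'
#' Per-cell S and G2M scores are the mean z-scored normalized expression of
#' the two gene sets; the phase is the argmax score if positive, else G1.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param s_genes,g2m_genes phase gene sets (defaults: bundled sets).
#' @return data.frame with \code{phase}, \code{s_score}, \code{g2m_score}.
#' @export
cellCyclePhase <- function(data, s_genes = cellCycleGenes()$S,
                           g2m_genes = cellCycleGenes()$G2M) {
    if (!length(s_genes) || !length(g2m_genes))
        stop("phase gene sets must be nonempty")
    logc <- assay(data, "logcounts")
    s_genes <- intersect(s_genes, rownames(logc))
    g2m_genes <- intersect(g2m_genes, rownames(logc))
    if (!length(s_genes) || !length(g2m_genes))
        stop("phase gene sets absent from data")
    s <- colMeans(rowZscore(logc[s_genes, , drop = FALSE]))
    g2m <- colMeans(rowZscore(logc[g2m_genes, , drop = FALSE]))
    phase <- ifelse(g2m > 0 & g2m >= s, "G2M",
                    ifelse(s > 0 & s > g2m, "S", "G1"))
    data.frame(phase = phase, s_score = s, g2m_score = g2m,
               row.names = colnames(data))
}

#' Equal-weight proliferation score
#'
#' Per-cell unweighted mean of the z-scored normalized expression of the
#' proliferation gene set (17 genes by default); a cell is "proliferating"
#' when its score is positive.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param genes proliferation gene set.
#' @param labels optional per-cell cluster/population labels; when given,
#'   the per-label proliferating fraction is reported.
#' @return List with \code{score}, \code{proliferating} and (optionally)
#'   \code{fraction_by_label}.
#' @export
proliferationScore <- function(data, genes = proliferationGenes(),
                               labels = NULL) {
    logc <- assay(data, "logcounts")
    missing <- setdiff(genes, rownames(logc))
    if (length(missing))
        stop("proliferation gene(s) missing: ",
             paste(missing, collapse = ", "))
    score <- colMeans(rowZscore(logc[genes, , drop = FALSE]))
    out <- list(score = score, proliferating = score > 0)
    if (!is.null(labels))
        out$fraction_by_label <- vapply(split(score > 0, labels), mean,
                                        numeric(1))
    out
}

#' Population fractions
#'
#' Label fractions, rounded to 0.1\% precision with largest-remainder
#' correction so they still sum to exactly 1.
#'
#' @param labels per-cell labels.
#' @return Named numeric fractions.
#' @export
populationFractions <- function(labels) {
    if (!length(labels)) stop("labels must be nonempty")
    tab <- table(labels)
    frac <- as.numeric(tab) / length(labels)
    names(frac) <- names(tab)
    largestRemainder(1000L, frac) / 1000
}
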