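## Patient-panel analysis: reference-gene normalization, age correction,
## variance filtering, patient subclustering, clinical enrichment ratios and
## two-group differential expression.

#' Normalize panel counts against reference genes
#'
#' Per sample, the scale is the geometric mean of the five reference-gene
#' counts; counts are multiplied by (cohort median scale / sample scale) and
#' log2(x + 1) transformed. This anchors all samples to the cohort-typical
#' RNA content while keeping values on the count scale.
#'
#' @param cohort A \linkS4class{PanelCohort}.
#' @param ref_genes reference gene ids (default: the cohort's flagged
#'   reference genes).
#' @return The cohort with an added \code{lognorm} assay;
#'   \code{metadata()$norm_factors} holds the per-sample factors and
#'   \code{metadata()$age_corrected} is set to FALSE.
#' @export
normalizeReferenceGenes <- function(cohort, ref_genes = refGeneIds(cohort)) {
    stopifnot(is(cohort, "PanelCohort"))
    if (!all(ref_genes %in% rownames(cohort)))
        stop("reference genes missing: ",
             paste(setdiff(ref_genes, rownames(cohort)), collapse = ", "))
    cts <- assay(cohort, "counts")
    refs <- cts[ref_genes, , drop = FALSE]
    dead <- colSums(refs > 0) == 0
    if (any(dead))
        stop("all-zero reference counts in sample(s): ",
             paste(colnames(cts)[dead], collapse = ", "))
    scale <- exp(colMeans(log(refs + (refs == 0))))   # geometric mean
    ## strictly: geometric mean over the reference counts; zero counts would
    ## zero the product, so they are left out via the +1[x==0] guard above
    factors <- stats::median(scale) / scale
    lognorm <- log2(sweep(cts, 2, factors, `*`) + 1)
    assay(cohort, "lognorm") <- lognorm
    metadata(cohort)$norm_factors <- factors
    metadata(cohort)$age_corrected <- FALSE
    cohort
}

#' Remove the linear age trend from normalized panel values
#'
#' Per gene, ordinary least squares of the normalized value on age; the
#' output is the residual plus the fitted value at the cohort mean age, so
#' values stay on the original scale but carry no linear age trend.
#'
#' @param panel A normalized \linkS4class{PanelCohort} (see
#'   \code{\link{normalizeReferenceGenes}}).
#' @param ages per-sample ages; defaults to \code{colData()$age}.
#' @return The panel with the \code{lognorm} assay age-corrected and
#'   \code{metadata()$age_corrected = TRUE}.
#' @export
correctAge <- function(panel, ages = colData(panel)$age) {
    stopifnot("lognorm" %in% assayNames(panel))
    if (length(unique(ages)) < 3 || ncol(panel) < 3)
        stop("age correction needs >= 3 samples with distinct ages")
    x <- assay(panel, "lognorm")
    a <- ages - mean(ages)
    slope <- (x %*% a) / sum(a^2)
    assay(panel, "lognorm") <- x - slope %*% rbind(a)
    metadata(panel)$age_corrected <- TRUE
    panel
}

#' Variance filtering of panel genes
#'
#' Returns the genes whose sample variance is at least the threshold
#' quantile of all gene variances (so the top set always contains the
#' maximal-variance gene). Deterministic given the data.
#'
#' @param panel A normalized \linkS4class{PanelCohort}, or a genes x samples
#'   matrix.
#' @param threshold variance-quantile threshold in [0, 1).
#' @param exclude_reference drop reference genes before filtering (only for
#'   PanelCohort input).
#' @return Character vector of retained gene ids.
#' @export
varianceFilter <- function(panel, threshold = 0.5,
                           exclude_reference = TRUE) {
    stopifnot(threshold >= 0, threshold < 1)
    x <- if (is(panel, "SummarizedExperiment")) {
        m <- assay(panel, "lognorm")
        if (exclude_reference && is(panel, "PanelCohort"))
            m <- m[!rowData(panel)$is_reference, , drop = FALSE]
        m
    } else panel
    if (nrow(x) == 0) stop("empty panel")
    v <- apply(x, 1, stats::var)
    if (threshold == 0) return(rownames(x))
    keep <- v >= stats::quantile(v, threshold)
    rownames(x)[keep]
}

#' Subcluster HF patients on a gene set
#'
#' Genes are z-scored across samples; HF samples are split into k clusters
#' by Ward hierarchical clustering (ward.D2 on Euclidean distance) of their
#' z-score vectors. Cluster ids are ordered so that cluster 2 has the higher
#' mean over the non-ACE2 signature genes (the severe-fibrosis cluster). A
#' deterministic 2-D embedding of all samples (first two principal
#' components of the z-scored gene set) is attached for visualization.
#'
#' @param panel A normalized \linkS4class{PanelCohort}.
#' @param genes gene subset to cluster on (e.g. the selected signature).
#' @param k number of HF clusters.
#' @return List with \code{labels} (per-sample: "donor", "1".."k"),
#'   \code{embedding} (samples x 2), \code{cluster_means} (genes x k
#'   z-score means), and \code{hclust}.
#' @export
clusterPatients <- function(panel, genes = fibrosisSignatureGenes(), k = 2) {
    stopifnot("lognorm" %in% assayNames(panel))
    missing <- setdiff(genes, rownames(panel))
    if (length(missing))
        stop("genes not in panel: ", paste(missing, collapse = ", "))
    hf <- colData(panel)$group == "HF"
    if (k > sum(hf)) stop("k exceeds the number of HF samples")
    z <- rowZscore(assay(panel, "lognorm")[genes, , drop = FALSE])
    emb <- stats::prcomp(t(z), center = FALSE)$x[, 1:2, drop = FALSE]
    colnames(emb) <- c("dim1", "dim2")

    hc <- stats::hclust(stats::dist(t(z[, hf, drop = FALSE])),
                        method = "ward.D2")
    raw <- stats::cutree(hc, k = k)
    ## order clusters by mean z over the non-ACE2 signature genes
    score_genes <- setdiff(intersect(genes, fibrosisSignatureGenes()),
                           "ACE2")
    if (!length(score_genes)) score_genes <- genes
    sev <- vapply(seq_len(k), function(cl)
        mean(z[score_genes, hf, drop = FALSE][, raw == cl, drop = FALSE]),
        numeric(1))
    relab <- match(seq_len(k), order(sev))
    labels <- rep("donor", ncol(panel))
    labels[hf] <- as.character(relab[raw])
    names(labels) <- colnames(panel)
    cluster_means <- vapply(seq_len(k), function(cl)
        rowMeans(z[, hf, drop = FALSE][, relab[raw] == cl, drop = FALSE]),
        numeric(nrow(z)))
    colnames(cluster_means) <- as.character(seq_len(k))
    list(labels = labels, embedding = emb, cluster_means = cluster_means,
         hclust = hc)
}

#' Clinical-feature enrichment between two patient clusters
#'
#' For each clinical flag, the percentage of flagged patients per cluster
#' and the cluster-2/cluster-1 enrichment ratio.
#'
#' @param labels per-sample labels as from \code{\link{clusterPatients}}
#'   (only samples labelled "1"/"2" are used).
#' @param flags data.frame of per-sample logical flags (same order as
#'   labels).
#' @return data.frame with \code{pct_cluster1}, \code{pct_cluster2},
#'   \code{ratio} and \code{undefined} (TRUE when pct_cluster1 = 0).
#' @export
enrichmentRatio <- function(labels, flags) {
    in1 <- labels == "1"; in2 <- labels == "2"
    if (!any(in1) || !any(in2)) stop("both clusters must be non-empty")
    res <- do.call(rbind, lapply(colnames(flags), function(f) {
        p1 <- 100 * mean(flags[in1, f])
        p2 <- 100 * mean(flags[in2, f])
        data.frame(feature = f, pct_cluster1 = p1, pct_cluster2 = p2,
                   ratio = if (p1 == 0) NA_real_ else p2 / p1,
                   undefined = p1 == 0)
    }))
    rownames(res) <- res$feature
    res
}

#' Two-group differential expression on panel values
#'
#' Per gene, a two-sided Welch t-test between the two sample groups on the
#' normalized values, with Benjamini-Hochberg q-values. Genes with zero
#' variance in both groups are skipped with a message.
#'
#' @param panel A normalized \linkS4class{PanelCohort}.
#' @param group_a,group_b logical/index vectors or label pairs selecting the
#'   two sample groups; defaults to donor vs HF.
#' @param exclude_reference drop reference genes first.
#' @return data.frame with \code{t}, \code{df}, \code{p}, \code{q},
#'   \code{mean_diff}; significant set is \code{q < 0.05}.
#' @export
twoGroupDE <- function(panel,
                       group_a = colData(panel)$group == "donor",
                       group_b = colData(panel)$group == "HF",
                       exclude_reference = TRUE) {
    stopifnot("lognorm" %in% assayNames(panel))
    x <- assay(panel, "lognorm")
    if (exclude_reference) x <- x[!rowData(panel)$is_reference, ,
                                  drop = FALSE]
    if (sum(group_a) < 2 || sum(group_b) < 2)
        stop("each group needs >= 2 samples")
    res <- rowWelchT(x, group_a, group_b)
    skipped <- attr(res, "skipped")
    if (length(skipped))
        message("skipped zero-variance gene(s): ",
                paste(skipped, collapse = ", "))
    res <- res[!rownames(res) %in% skipped, ]
    res$q <- bhAdjust(res$p)
    res
}
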