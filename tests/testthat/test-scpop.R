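## Single-cell processing: QC, doublets, normalization, clustering,
## markers, classification, scores.

test_that("gene QC requires both layers to clear the threshold", {
    sp <- rbind(a = c(13, 12), b = c(10, 9), c = c(13, 12))
    un <- rbind(a = c(13, 12), b = c(13, 12), c = c(10, 9))
    colnames(sp) <- colnames(un) <- c("c1", "c2")
    sc <- SCCultureData(sp, un, batch = factor(c(1, 1)))
    expect_identical(rownames(qcFilterGenes(sc, 20)), "a")
    expect_identical(nrow(qcFilterGenes(sc, 0)), 3L)
    expect_error(qcFilterGenes(sc, 1000), "all genes")
})

test_that("constructed midpoint cells get the top doublet scores", {
    blobs <- toyBlobs(n_per = 100, shift = 12)
    sp <- spliced(blobs)
    ## append synthetic midpoint cells = sums of an A and a B cell
    mid <- sp[, 1:15] + sp[, 101:115]
    colnames(mid) <- sprintf("mid%02d", 1:15)
    sc <- SCCultureData(cbind(sp, mid), cbind(sp, mid),
                        batch = factor(rep(1, 215)))
    ds <- doubletScore(sc, k = 15, n_pcs = 5, seed = 0)
    is_mid <- startsWith(colnames(sc), "mid")
    expect_gt(mean(ds$score[is_mid]), mean(ds$score[!is_mid]))
    ## the highest-scored cells are dominated by the midpoints
    top <- order(-ds$score)[1:15]
    expect_gte(sum(is_mid[top]), 12)
})

test_that("doublet-free data is flagged at most at the nominal rate", {
    sc <- generateCultureData(cultureConfig(n_cells = 600,
                                            doublet_rate = 0, seed = 2))
    ds <- doubletScore(sc, k = 20, threshold = 0.98, seed = 0)
    expect_lte(mean(ds$flagged), 1 - 0.98 + 0.01)
})

test_that("injected doublets score higher than singlets", {
    sc <- generateCultureData(cultureConfig(n_cells = 1000,
                                            doublet_rate = 0.05, seed = 0))
    ds <- doubletScore(sc, seed = 0)
    truth <- colData(sc)$is_doublet
    expect_gt(mean(ds$score[truth]), mean(ds$score[!truth]))
})

test_that("normalization scales cells to the median total before log1p", {
    sp <- cbind(c1 = c(10, 10), c2 = c(20, 20), c3 = c(40, 40))
    rownames(sp) <- c("g1", "g2")
    sc <- SCCultureData(sp, sp, batch = factor(rep(1, 3)))
    sc <- preprocessCells(sc, n_hvg = 2, n_pcs = 1, k = 1)
    logc <- assay(sc, "logcounts")
    ## median total is 40; the cell with double that is halved
    expect_equal(unname(logc["g1", "c3"]), log1p(40 * 40 / 80))
    expect_equal(unname(logc["g1", "c1"]), log1p(10 * 40 / 20))
    expect_identical(unname(log1p(0)), 0)
})

test_that("identical cells collapse to a single point in PC space", {
    sp <- matrix(5, 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
    sc <- SCCultureData(sp, sp, batch = factor(rep(1, 10)))
    sc <- preprocessCells(sc, n_hvg = 4, n_pcs = 2, k = 2)
    pca <- SingleCellExperiment::reducedDim(sc, "PCA")
    expect_lt(max(dist(pca)), 1e-10)
})

test_that("Louvain clustering separates two blobs and respects resolution", {
    blobs <- preprocessCells(toyBlobs(), n_hvg = 40, n_pcs = 5, k = 10)
    ## the blobs are fully separated (disconnected kNN graph): at a low
    ## resolution each component is one community
    cl <- clusterCells(blobs, resolution = 0.1, seed = 0)
    expect_identical(nlevels(cl), 2L)
    expect_equal(mclust::adjustedRandIndex(cl, colData(blobs)$population),
                 1)
    ## resolution -> 0 on a connected graph collapses to one community
    one <- toyBlobs(n_per = 60, shift = 0)
    one <- preprocessCells(one, n_hvg = 40, n_pcs = 5, k = 10)
    tiny <- clusterCells(one, resolution = 1e-4, seed = 0)
    expect_identical(nlevels(tiny), 1L)
})

test_that("cluster markers rank exclusive genes first", {
    blobs <- preprocessCells(toyBlobs(), n_hvg = 40, n_pcs = 5, k = 10)
    mk <- clusterMarkers(blobs, colData(blobs)$population, top_n = 5)
    a_top <- mk$gene[mk$cluster == "A"]
    b_top <- mk$gene[mk$cluster == "B"]
    ## genes 1..20 are elevated in A, 21..40 in B by construction
    expect_true(all(a_top %in% sprintf("g%02d", 1:20)))
    expect_true(all(b_top %in% sprintf("g%02d", 21:40)))
})

test_that("marker t statistics equal the closed-form Welch value", {
    blobs <- preprocessCells(toyBlobs(n_per = 20), n_hvg = 40, n_pcs = 5,
                             k = 5)
    mk <- clusterMarkers(blobs, colData(blobs)$population, top_n = 3)
    logc <- assay(blobs, "logcounts")
    lab <- colData(blobs)$population
    g <- mk$gene[1]
    tt <- t.test(logc[g, lab == mk$cluster[1]],
                 logc[g, lab != mk$cluster[1]])
    expect_equal(mk$t[1], unname(tt$statistic), tolerance = 1e-12)
})

test_that("marker detection is label-permutation equivariant", {
    blobs <- preprocessCells(toyBlobs(), n_hvg = 40, n_pcs = 5, k = 10)
    lab <- colData(blobs)$population
    m1 <- clusterMarkers(blobs, lab, top_n = 5)
    swapped <- ifelse(lab == "A", "B", "A")
    m2 <- clusterMarkers(blobs, swapped, top_n = 5)
    expect_identical(m1$gene[m1$cluster == "A"],
                     m2$gene[m2$cluster == "B"])
})

test_that("marker-rule typing follows the precedence order", {
    sc <- fixtureSmallCulture()
    ct <- classifyCellTypes(sc)
    pop <- colData(sc)$population
    ## per-cell rule recovers the generator populations
    mp <- !is.na(pop) & pop %in% c("MP1", "MP2")
    fbp <- !is.na(pop) & startsWith(pop, "FB")
    expect_gt(mean(ct$label[mp] == "macrophage"), 0.95)
    expect_gt(mean(ct$label[fbp] == "fibroblast"), 0.95)
    ## planted double positives produce flagged macrophages
    expect_gt(sum(ct$acta2_positive), 0)
    expect_error(classifyCellTypes(sc, markers = list(endothelial = "NOPE",
                                                      macrophage = "Lyz2",
                                                      fibroblast = "Acta2")),
                 "missing")
})

test_that("fibroblast state rule ties break to contractile", {
    ## two genes per set, engineered so one cell ties exactly
    logc <- rbind(Col1a1 = c(2, 0, 1), Col1a2 = c(2, 0, 1),
                  Col3a1 = c(2, 0, 1),
                  Acta2 = c(0, 2, 1), Tpm2 = c(0, 2, 1))
    colnames(logc) <- c("m", "c", "tie")
    sc <- SCCultureData(matrix(1, 5, 3, dimnames = dimnames(logc)),
                        matrix(1, 5, 3, dimnames = dimnames(logc)),
                        batch = factor(rep(1, 3)))
    assay(sc, "logcounts") <- logc
    st <- classifyFbState(sc, rep(TRUE, 3))
    expect_identical(unname(st$state),
                     c("matrix_producing", "contractile", "contractile"))
})

test_that("cell-cycle phases derive from set scores with G1 fallback", {
    genes <- c(cellCycleGenes()$S, cellCycleGenes()$G2M)
    n <- length(genes)
    logc <- matrix(1, n, 3, dimnames = list(genes, c("flat", "g2m", "s")))
    logc[cellCycleGenes()$G2M, "g2m"] <- 3
    logc[cellCycleGenes()$S, "s"] <- 3
    sc <- SCCultureData(matrix(1, n, 3, dimnames = dimnames(logc)),
                        matrix(1, n, 3, dimnames = dimnames(logc)),
                        batch = factor(rep(1, 3)))
    assay(sc, "logcounts") <- logc
    ph <- cellCyclePhase(sc)
    expect_identical(ph["flat", "phase"], "G1")
    expect_identical(ph["g2m", "phase"], "G2M")
    expect_identical(ph["s", "phase"], "S")
})

test_that("FB4 is the cycling population on synthetic data", {
    sc <- fixtureSmallCulture()
    pop <- colData(sc)$population
    ph <- cellCyclePhase(sc)
    fb4 <- which(!is.na(pop) & pop == "FB4")
    expect_gt(mean(ph$phase[fb4] == "G2M"), 0.5)
    pr <- proliferationScore(sc, labels = pop)
    fr <- pr$fraction_by_label[paste0("FB", 1:6)]
    expect_identical(names(which.max(fr)), "FB4")
    expect_true(all(sort(names(sort(fr)[1:2])) == c("FB1", "FB3")))
})

test_that("proliferation score is an equal-weight z mean", {
    genes <- proliferationGenes()
    n <- length(genes)
    logc <- matrix(rep(c(1, 2, 3), each = n), n, 3,
                   dimnames = list(genes, c("lo", "mid", "hi")))
    ## one gene up, one gene down by the same z leaves the score at 0
    logc[1, ] <- c(1, 3, 2)
    logc[2, ] <- c(3, 1, 2)
    sc <- SCCultureData(matrix(1, n, 3, dimnames = dimnames(logc)),
                        matrix(1, n, 3, dimnames = dimnames(logc)),
                        batch = factor(rep(1, 3)))
    assay(sc, "logcounts") <- logc
    pr <- proliferationScore(sc)
    expect_equal(unname(pr$score["mid"]), 0, tolerance = 1e-12)
    expect_error(proliferationScore(sc, genes = c(genes, "Missing1")),
                 "Missing1")
})

test_that("population fractions are rounding-corrected to sum 1", {
    pf <- populationFractions(rep(c("a", "b", "c"), c(1, 1, 1)))
    expect_equal(unname(pf), c(0.334, 0.333, 0.333))
    expect_equal(sum(pf), 1)
    expect_identical(unname(populationFractions(rep("x", 5))), 1)
})
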