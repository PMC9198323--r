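## Generator contracts: shapes, ground truth, reproducibility.

test_that("patient cohort has the study dimensions and structure", {
    co <- fixtureCohort()$raw
    expect_identical(dim(co), c(87L, 75L))        # 82 panel + 5 reference
    expect_identical(sum(!rowData(co)$is_reference), 82L)
    expect_identical(as.vector(table(colData(co)$group)[c("donor", "HF")]),
                     c(10L, 65L))
    expect_true(all(fibrosisSignatureGenes() %in% rownames(co)))
    expect_true(all(is.na(colData(co)$true_subcluster[
        colData(co)$group == "donor"])))
    expect_setequal(unique(stats::na.omit(colData(co)$true_subcluster)),
                    c(1L, 2L))
})

test_that("generators are reproducible for identical config and seed", {
    a <- generatePatientCohort(cohortConfig(seed = 7))
    b <- generatePatientCohort(cohortConfig(seed = 7))
    expect_identical(assay(a, "counts"), assay(b, "counts"))
    c1 <- generateCultureData(cultureConfig(n_cells = 300, seed = 3))
    c2 <- generateCultureData(cultureConfig(n_cells = 300, seed = 3))
    expect_identical(spliced(c1), spliced(c2))
    expect_identical(unspliced(c1), unspliced(c2))
})

test_that("null cohort carries no group signal", {
    co <- generatePatientCohort(cohortConfig(hf_log2fc = 0,
                                             cluster2_log2fc = 0,
                                             seed = 2))
    np <- normalizeReferenceGenes(co)
    de <- twoGroupDE(np)
    expect_lte(sum(de$q < 0.05), 2)     # nominal false positives only
})

test_that("culture population sizes follow largest-remainder rounding", {
    cfg <- cultureConfig(n_cells = 997, doublet_rate = 0, seed = 1)
    sc <- generateCultureData(cfg)
    sizes <- table(colData(sc)$population)
    expect_identical(sum(sizes), 997L)
    expected <- fibrosig:::largestRemainder(997, cfg$population_fractions)
    expect_identical(as.integer(sizes[names(expected)]),
                     unname(expected))
})

test_that("doublet_rate = 0 yields no flagged ground-truth doublets", {
    sc <- generateCultureData(cultureConfig(n_cells = 300,
                                            doublet_rate = 0, seed = 1))
    expect_identical(sum(colData(sc)$is_doublet), 0L)
    expect_identical(ncol(sc), 300L)
})

test_that("planted population markers are elevated in their population", {
    sc <- fixtureSmallCulture()
    logc <- assay(sc, "logcounts")
    pop <- colData(sc)$population
    mk <- cultureMarkerGenes()
    fc <- cultureConfig()$marker_log2fc
    for (p in c("FB1", "FB3", "FB6", "MP1")) {
        for (g in intersect(mk[[p]], rownames(logc))) {
            gap <- mean(logc[g, which(pop == p)]) - mean(logc[g, ])
            expect_gt(gap, log1p(2^(fc / 2) * 0.01) - log1p(0.01))
        }
    }
})

test_that("TGFb isoforms split between macrophages and fibroblasts", {
    sc <- fixtureSmallCulture()
    logc <- assay(sc, "logcounts")
    pop <- colData(sc)$population
    mp <- which(pop %in% c("MP1", "MP2"))
    fb <- which(!is.na(pop) & startsWith(pop, "FB"))
    expect_gt(mean(logc["Tgfb1", mp]), mean(logc["Tgfb1", fb]))
    expect_lt(mean(logc["Tgfb2", mp]), mean(logc["Tgfb2", fb]))
    expect_lt(mean(logc["Tgfb3", mp]), mean(logc["Tgfb3", fb]))
})

test_that("steady-state unspliced/spliced ratio matches the rate ratio", {
    ## macrophages sit at kinetic steady state: mean(u)/mean(s) -> gamma/beta
    sc <- generateCultureData(cultureConfig(n_cells = 2500,
                                            doublet_rate = 0, seed = 4))
    mp <- which(colData(sc)$population == "MP1")
    ms <- rowMeans(spliced(sc)[, mp])
    mu <- rowMeans(unspliced(sc)[, mp])
    keep <- ms > 5
    ratio <- mu[keep] / ms[keep]
    truth <- (rowData(sc)$gamma / rowData(sc)$beta)[keep]
    expect_lt(median(abs(ratio / truth - 1)), 0.05)
})

test_that("bulk time course mixes signatures per stage weights", {
    sc <- generateCultureData(cultureConfig(n_cells = 400, seed = 0))
    sig <- populationSignatures(sc)
    cfg <- timecourseConfig(seed = 0)
    bulk <- generateBulkTimecourse(cfg, sig)
    expect_identical(ncol(bulk), 20L)   # 5 stages x 4 replicates
    expect_identical(levels(stageLabels(bulk)),
                     c("uninjured", "3d", "7d", "2w", "later"))
    ## recompute expected stage means from the mixture weights (oracle)
    w <- cfg$mixing_weights
    expected <- sig[, colnames(w)] %*% t(w)
    ## FB4 markers peak at 3d, FB6 markers at 7d in the expected profile
    fb4 <- intersect(cultureMarkerGenes()$FB4, rownames(expected))
    fb6 <- intersect(cultureMarkerGenes()$FB6, rownames(expected))
    zrow <- function(m) t(scale(t(m)))
    expect_identical(
        colnames(expected)[apply(zrow(expected[fb4, ]), 1, which.max)],
        rep("3d", length(fb4)))
    expect_identical(
        colnames(expected)[apply(zrow(expected[fb6, ]), 1, which.max)],
        rep("7d", length(fb6)))
})

test_that("identical stage weights yield an empty ANOVA DE set", {
    sc <- generateCultureData(cultureConfig(n_cells = 400, seed = 0))
    sig <- populationSignatures(sc)
    w0 <- matrix(1 / 6, 5, 6,
                 dimnames = list(c("uninjured", "3d", "7d", "2w", "later"),
                                 paste0("FB", 1:6)))
    b0 <- generateBulkTimecourse(timecourseConfig(mixing_weights = w0,
                                                  seed = 5), sig)
    de <- anovaDE(b0)
    expect_lte(length(de$de_genes), ceiling(0.01 * nrow(b0)))
})

test_that("invalid configurations are rejected", {
    expect_error(cohortConfig(n_patients = 0), "positive")
    expect_error(cohortConfig(cluster2_fraction = 1), "cluster2_fraction")
    expect_error(cohortConfig(informative_gene_names = "NOSUCH"),
                 "not in panel")
    bad <- .default <- cultureConfig()$population_fractions
    bad[1] <- bad[1] + 0.1
    expect_error(cultureConfig(population_fractions = bad), "sum to 1")
    expect_error(timecourseConfig(stages = c("a", "a", "b")), "unique")
})
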