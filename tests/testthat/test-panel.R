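## Reference-gene normalization, age correction, variance filter,
## patient clustering, enrichment ratios, two-group DE.

test_that("identical reference counts give unit factors", {
    counts <- matrix(c(10, 20, 30, 40), 2, 2,
                     dimnames = list(c("gA", "gB"), c("s1", "s2")))
    co <- toyCohort(counts)
    np <- normalizeReferenceGenes(co)
    expect_equal(unname(metadata(np)$norm_factors), c(1, 1))
    expect_equal(assay(np, "lognorm")["gA", ], log2(counts["gA", ] + 1),
                 ignore_attr = TRUE)
    ## zero counts transform to zero
    counts0 <- counts; counts0[1, 1] <- 0
    np0 <- normalizeReferenceGenes(toyCohort(counts0))
    expect_identical(assay(np0, "lognorm")["gA", "s1"], 0)
})

test_that("normalization follows the geometric-mean/median-anchor rule", {
    ## reference geomeans 100 and 200, median scale 150: a count of 10 in
    ## the low sample becomes 15, so the value is log2(16) = 4
    refs <- paste0("REF", 1:2)
    mat <- rbind(gA = c(10, 10),
                 matrix(c(100, 100, 200, 200), 2, 2,
                        dimnames = list(refs, NULL)))
    colnames(mat) <- c("s1", "s2")
    co <- PanelCohort(mat, group = c("donor", "HF"), age = c(40, 50),
                      ref_genes = refs)
    np <- normalizeReferenceGenes(co)
    expect_equal(unname(metadata(np)$norm_factors), c(150 / 100, 150 / 200))
    expect_equal(assay(np, "lognorm")["gA", "s1"], log2(10 * 1.5 + 1))
})

test_that("all-zero reference counts raise an error naming the sample", {
    refs <- paste0("REF", 1:2)
    mat <- rbind(gA = c(10, 10),
                 matrix(c(0, 0, 200, 200), 2, 2,
                        dimnames = list(refs, NULL)))
    colnames(mat) <- c("bad1", "s2")
    co <- PanelCohort(mat, group = c("donor", "HF"), age = c(40, 50),
                      ref_genes = refs)
    expect_error(normalizeReferenceGenes(co), "bad1")
})

test_that("scaling a whole sample leaves normalized values unchanged", {
    co <- fixtureCohort()$raw
    cts <- assay(co, "counts")
    cts2 <- cts; cts2[, 3] <- cts2[, 3] * 4
    co2 <- PanelCohort(cts2, group = colData(co)$group,
                       age = colData(co)$age)
    v1 <- assay(normalizeReferenceGenes(co), "lognorm")[, 3]
    v2 <- assay(normalizeReferenceGenes(co2), "lognorm")[, 3]
    ## exact up to the +1 pseudocount at large counts
    big <- assay(co, "counts")[, 3] > 100
    expect_lt(max(abs(v1[big] - v2[big])), 0.02)
})

test_that("age correction removes an exactly linear age trend", {
    ages <- c(30, 40, 50, 60)
    counts <- matrix(100, 2, 4,
                     dimnames = list(c("gA", "gB"),
                                     paste0("s", 1:4)))
    co <- toyCohort(counts, age = ages)
    np <- normalizeReferenceGenes(co)
    x <- assay(np, "lognorm")
    x["gA", ] <- 2 + 0.05 * ages          # exactly linear gene
    assay(np, "lognorm") <- x
    out <- correctAge(np, ages)
    expect_equal(unname(assay(out, "lognorm")["gA", ]),
                 rep(2 + 0.05 * mean(ages), 4))
    expect_true(metadata(out)$age_corrected)
    ## slope-zero gene is untouched
    expect_equal(assay(out, "lognorm")["gB", ], x["gB", ])
})

test_that("post-correction age slopes are numerically zero", {
    np <- fixtureCohort()$norm
    ages <- colData(np)$age
    a <- ages - mean(ages)
    slopes <- (assay(np, "lognorm") %*% a) / sum(a^2)
    expect_lt(max(abs(slopes)), 1e-10)
})

test_that("age correction needs at least 3 distinct ages", {
    counts <- matrix(100, 2, 2, dimnames = list(c("gA", "gB"), c("a", "b")))
    np <- normalizeReferenceGenes(toyCohort(counts))
    expect_error(correctAge(np, c(40, 50)), ">= 3")
})

test_that("variance filter follows the quantile rule", {
    x <- matrix(0, 3, 5, dimnames = list(c("g1", "g2", "g3"), NULL))
    x[1, ] <- c(1, 2, 3, 4, 5) * sqrt(1 / 2.5)        # var 1
    x[2, ] <- c(1, 2, 3, 4, 5) * sqrt(2 / 2.5)        # var 2
    x[3, ] <- c(1, 2, 3, 4, 5) * sqrt(3 / 2.5)        # var 3
    expect_setequal(varianceFilter(x, 0), c("g1", "g2", "g3"))
    expect_setequal(varianceFilter(x, 0.5), c("g2", "g3"))
    expect_setequal(varianceFilter(x, 0.999), "g3")
})

test_that("patient clustering recovers the planted subclusters", {
    np <- fixtureCohort()$norm
    cl <- clusterPatients(np, fibrosisSignatureGenes(), k = 2)
    hf <- colData(np)$group == "HF"
    ari <- mclust::adjustedRandIndex(cl$labels[hf],
                                     colData(np)$true_subcluster[hf])
    expect_gte(ari, 0.9)
    ## all signature genes except ACE2 higher in cluster 2
    cm <- cl$cluster_means[fibrosisSignatureGenes(), ]
    up <- cm[, "2"] > cm[, "1"]
    expect_true(all(up[setdiff(fibrosisSignatureGenes(), "ACE2")]))
    expect_false(up["ACE2"])
})

test_that("cluster labels are invariant under sample permutation", {
    np <- fixtureCohort()$norm
    cl1 <- clusterPatients(np, k = 2)
    perm <- sample(ncol(np))
    cl2 <- clusterPatients(np[, perm], k = 2)
    expect_identical(cl1$labels[colnames(np)[perm]], cl2$labels)
})

test_that("enrichment ratios follow the percentage rule", {
    labels <- rep(c("1", "2"), c(50, 25))
    flags <- data.frame(
        ischemic = c(rep(TRUE, 23), rep(FALSE, 27),   # 46% of cluster 1
                     rep(TRUE, 21), rep(FALSE, 4)),   # 84% of cluster 2
        never = rep(FALSE, 75))
    er <- enrichmentRatio(labels, flags)
    expect_equal(er["ischemic", "pct_cluster1"], 46)
    expect_equal(er["ischemic", "pct_cluster2"], 84)
    expect_equal(er["ischemic", "ratio"], 84 / 46, tolerance = 1e-12)
    expect_true(er["never", "undefined"])
    ## equal percentages give ratio 1
    er2 <- enrichmentRatio(labels, data.frame(all = rep(TRUE, 75)))
    expect_equal(er2["all", "ratio"], 1)
})

test_that("two-group DE recovers planted fibrosis genes", {
    fix <- fixtureCohort()
    de <- twoGroupDE(fix$norm)
    truth <- rownames(fix$raw)[rowData(fix$raw)$hf_effect]
    hits <- rownames(de)[de$q < 0.05]
    expect_gte(mean(truth %in% hits), 0.8)                 # recall
    expect_lte(mean(!hits %in% truth), 0.1)                # empirical FDR
})

test_that("per-gene Welch t matches stats::t.test", {
    np <- fixtureCohort()$norm
    de <- twoGroupDE(np)
    x <- assay(np, "lognorm")
    g <- colData(np)$group
    for (gene in rownames(de)[c(1, 20, 50)]) {
        tt <- t.test(x[gene, g == "donor"], x[gene, g == "HF"])
        expect_equal(de[gene, "t"], unname(tt$statistic), tolerance = 1e-12)
        expect_equal(de[gene, "p"], tt$p.value, tolerance = 1e-12)
    }
})
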