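## Steady-state velocity: gamma fits, velocity signs, graph cosines,
## embedded arrows.

.velToy <- function(s, u) {
    ## wrap vectors as a 1-gene SCCultureData with precomputed smoothing
    n <- length(s)
    sc <- SCCultureData(matrix(s, 1, n, dimnames = list("g", paste0("c", 1:n))),
                        matrix(u, 1, n, dimnames = list("g", paste0("c", 1:n))),
                        batch = factor(rep(1, n)))
    assay(sc, "Ms") <- spliced(sc)
    assay(sc, "Mu") <- unspliced(sc)
    sc
}

test_that("gamma fits the regression-through-origin on extreme cells", {
    ## u = 2s exactly
    sc <- .velToy(s = c(1, 2, 3, 4, 5), u = c(2, 4, 6, 8, 10))
    vm <- fitGamma(sc, q = 0.2, min_extreme = 2)
    expect_equal(unname(vm$gamma["g"]), 2)
    ## 5-cell toy: extremes {s=0, s=4} -> gamma = (0 + 32) / (0 + 16) = 2
    sc2 <- .velToy(s = c(0, 1, 2, 3, 4), u = c(0, 1, 2, 3, 8))
    vm2 <- fitGamma(sc2, q = 0.2, min_extreme = 2)
    expect_equal(unname(vm2$gamma["g"]), 2)
    ## constant positive s: single extreme set, gamma = mean(u)/s
    sc3 <- .velToy(s = rep(2, 5), u = c(1, 2, 3, 4, 5))
    vm3 <- fitGamma(sc3, q = 0.2, min_extreme = 2)
    expect_equal(unname(vm3$gamma["g"]), mean(c(1, 2, 3, 4, 5)) / 2)
    ## all-zero s is flagged unfitted
    sc4 <- .velToy(s = rep(0, 5), u = 1:5)
    vm4 <- fitGamma(sc4, q = 0.2, min_extreme = 2)
    expect_false(vm4$fitted["g"])
})

test_that("gamma is scale equivariant in u and s", {
    set.seed(1)
    s <- rpois(50, 20); u <- 0.4 * s + rnorm(50, 0, 0.5)
    g0 <- fitGamma(.velToy(s, u))$gamma
    expect_equal(unname(fitGamma(.velToy(s, 3 * u))$gamma), unname(3 * g0))
    expect_equal(unname(fitGamma(.velToy(2 * s, u))$gamma), unname(g0 / 2))
})

test_that("velocity is zero at steady state and positive under induction", {
    sc <- .velToy(s = c(0, 1, 2, 3, 4), u = c(0, 1, 2, 3, 8))
    vm <- fitGamma(sc, q = 0.2, min_extreme = 2)
    v <- computeVelocity(sc, vm)
    expect_equal(unname(v["g", 5]), 8 - 2 * 4)           # the toy cell
    sc2 <- .velToy(s = 1:5, u = 2 * (1:5))
    v2 <- computeVelocity(sc2, fitGamma(sc2, q = 0.2, min_extreme = 2))
    expect_equal(unname(v2["g", ]), rep(0, 5))
    ## u above the steady-state line -> positive velocity
    expect_gt(v["g", 5] + 1e-12, 0)
    sc3 <- .velToy(s = c(1, 2, 3, 4, 5), u = c(2, 4, 6, 8, 11))
    v3 <- computeVelocity(sc3, fitGamma(sc3, q = 0.2, min_extreme = 2))
    expect_gt(v3["g", 5], 0)
})

test_that("steady-state noise gives near-zero mean velocity", {
    set.seed(2)
    n <- 800
    gamma_true <- 0.5
    s <- matrix(rpois(5 * n, 50), 5, n)
    u <- gamma_true * s + matrix(rnorm(5 * n, 0, 2), 5, n)
    dimnames(s) <- dimnames(u) <- list(paste0("g", 1:5), paste0("c", 1:n))
    sc <- SCCultureData(pmax(s, 0), pmax(u, 0),
                        batch = factor(rep(1, n)))
    assay(sc, "Ms") <- s; assay(sc, "Mu") <- u
    vm <- fitGamma(sc)
    v <- computeVelocity(sc, vm)
    ## include the gamma-fit uncertainty (se(gamma) * mean(s)) in the s.e.
    tol <- vapply(rownames(v), function(g) {
        sg <- s[g, ]
        ext <- which(sg <= quantile(sg, 0.05) | sg >= quantile(sg, 0.95))
        se_g <- vm$resid_sd[g] / sqrt(sum(sg[ext]^2))
        3 * sqrt(var(v[g, ]) / n + (se_g * mean(sg))^2)
    }, numeric(1))
    expect_true(all(abs(rowMeans(v)) < tol + 1e-8))
})

test_that("edge cosines follow the dot-product geometry", {
    ## 3 cells on a line in 2-gene space; velocities set by hand
    x <- log1p(rbind(g1 = c(1, 3, 1), g2 = c(1, 1, 3)))
    sc <- SCCultureData(matrix(1, 2, 3, dimnames = dimnames(x)),
                        matrix(1, 2, 3, dimnames = dimnames(x)),
                        batch = factor(rep(1, 3)))
    assay(sc, "Ms") <- expm1(x)
    assay(sc, "Mu") <- expm1(x)
    metadata(sc)$knn <- rbind(c(2, 3), c(1, 3), c(1, 2))
    v <- matrix(0, 2, 3, dimnames = dimnames(x))
    d12 <- x[, 2] - x[, 1]
    v[, 1] <- d12                       # parallel to the displacement to c2
    g <- velocityGraph(sc, v)
    expect_equal(g$cos[1, 1], 1)
    ## antiparallel
    v[, 1] <- -d12
    g2 <- velocityGraph(sc, v)
    expect_equal(g2$cos[1, 1], -1)
    ## orthogonal toy vectors
    v[, 1] <- c(-d12[2], d12[1])
    g3 <- velocityGraph(sc, v)
    expect_equal(g3$cos[1, 1], 0, tolerance = 1e-12)
    ## zero-velocity cells get zero cosines
    v[, 1] <- 0
    expect_equal(velocityGraph(sc, v)$cos[1, ], c(0, 0))
})

test_that("embedded arrows follow the softmax transition rule", {
    emb <- rbind(c(0, 0), c(1, 0), c(-1, 0))
    nn <- rbind(c(2, 3), c(1, 3), c(1, 2))
    ## equal cosines cancel exactly
    g <- structure(list(nn = nn, cos = rbind(c(0.5, 0.5), c(0, 0),
                                             c(0, 0))),
                   class = "VelocityGraph")
    ar <- embedVelocity(g, emb)
    expect_equal(ar[1, ], c(dx = 0, dy = 0))
    ## strong preference for the right neighbour points the arrow right
    g$cos[1, ] <- c(1, -1)
    ar2 <- embedVelocity(g, emb, sigma = 0.1)
    expect_gt(ar2[1, "dx"], 0.9)
    expect_equal(unname(ar2[1, "dy"]), 0)
})

test_that("branched culture velocities point from FB2 toward FB3/FB4", {
    sc <- generateCultureData(cultureConfig(n_cells = 2500,
                                            doublet_rate = 0, seed = 0))
    sc <- preprocessCells(qcFilterGenes(sc))
    sc <- smoothCounts(sc, 30)
    vm <- fitGamma(sc)
    v <- computeVelocity(sc, vm)
    vg <- velocityGraph(sc, v)
    emb <- SingleCellExperiment::reducedDim(sc, "EMB")
    ar <- embedVelocity(vg, emb)
    pop <- colData(sc)$population
    cent <- apply(emb, 2, function(cc) tapply(cc, pop, mean))
    target <- colMeans(cent[c("FB3", "FB4"), ])
    fb2 <- which(pop == "FB2")
    proj <- rowSums(ar[fb2, ] *
                    cbind(target[1] - emb[fb2, 1], target[2] - emb[fb2, 2]))
    expect_gte(mean(proj > 0), 0.7)
})
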