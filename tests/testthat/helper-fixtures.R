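## Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, .fixture_cache))
        assign(key, force(expr), .fixture_cache)
    get(key, .fixture_cache)
}

## Default synthetic cohort plus its normalized/age-corrected form.
fixtureCohort <- function() cached("cohort", {
    co <- generatePatientCohort(cohortConfig(seed = 0))
    list(raw = co, norm = correctAge(normalizeReferenceGenes(co)))
})

## Small culture dataset (fast) for unit tests.
fixtureSmallCulture <- function() cached("small_culture", {
    sc <- generateCultureData(cultureConfig(n_cells = 1200, seed = 0))
    sc <- qcFilterGenes(sc)
    preprocessCells(sc)
})

## A hand-built PanelCohort with controllable counts.
toyCohort <- function(counts, age = NULL, group = NULL) {
    refs <- paste0("REF", 1:2)
    n <- ncol(counts)
    mat <- rbind(counts,
                 matrix(100, 2, n, dimnames = list(refs, colnames(counts))))
    PanelCohort(mat,
                group = if (is.null(group))
                    rep(c("donor", "HF"), length.out = n) else group,
                age = if (is.null(age)) seq(40, 40 + n - 1) else age,
                ref_genes = refs)
}

## Two well-separated Gaussian blobs as an SCCultureData (for clustering
## and doublet construction oracles).
toyBlobs <- function(n_per = 60, n_genes = 40, shift = 6, seed = 1) {
    set.seed(seed)
    mu <- matrix(5, n_genes, 2)
    mu[seq_len(n_genes / 2), 1] <- 5 + shift
    mu[seq(n_genes / 2 + 1, n_genes), 2] <- 5 + shift
    lab <- rep(c("A", "B"), each = n_per)
    counts <- vapply(seq_along(lab), function(i)
        rpois(n_genes, mu[, ifelse(lab[i] == "A", 1, 2)]),
        numeric(n_genes))
    dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)),
                             sprintf("c%03d", seq_along(lab)))
    out <- SCCultureData(counts, counts, batch = factor(rep(1, length(lab))),
                         population = lab)
    out
}
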