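## Synthetic cultured-cell scRNA-seq generator. Emulates a 15-day primary
## cardiac-fibroblast culture: a large fibroblast compartment laid out along
## a branched activation trajectory (FB2 -> FB1; FB2 -> FB3/FB4 -> FB5 ->
## FB6), two macrophage populations and a small endothelial population.
## Spliced and unspliced layers are integrated from two-state transcription
## kinetics along each cell's lineage path, so unspliced counts lead spliced
## counts during induction and the steady-state velocity sign is positive
## for genes being switched on along a branch.

.default_population_fractions <- function() {
    fb_total <- 1 - 0.249 - 0.0089
    fb_share <- c(FB1 = 0.06, FB2 = 0.14, FB3 = 0.257, FB4 = 0.15,
                  FB5 = 0.223, FB6 = 0.17)
    c(EC = 0.0089, MP1 = 0.6 * 0.249, MP2 = 0.4 * 0.249,
      fb_total * fb_share)
}

#' Configuration for the synthetic cell-culture dataset
#'
#' Defaults emulate the reported culture composition: endothelial cells
#' 0.89\%, macrophages 24.9\% (split 60/40 into MP1/MP2), fibroblasts the
#' rest, with FB3 = 25.7\% and FB5 = 22.3\% of fibroblasts and the
#' free shares (FB1, FB2, FB4, FB6) calibrated so the matrix-producing
#' phenotype covers 76\% of fibroblasts. The branch topology
#' is fixed: FB2 -> FB1, FB2 -> FB3 -> FB5 -> FB6 and FB2 -> FB4 -> FB5 ->
#' FB6.
#'
#' @param n_cells number of singlet cells (doublets are appended on top).
#' @param population_fractions named fractions over EC, MP1, MP2, FB1..FB6;
#'   must sum to 1.
#' @param n_genes total gene count (>= the named marker genes; the rest are
#'   background genes Gm...).
#' @param marker_log2fc log2 elevation of each population's unique markers.
#' @param doublet_rate fraction of n_cells appended as ground-truth doublets
#'   (sums of two random singlets).
#' @param n_batches number of batches; \code{batch_sd} is the per-gene log2
#'   s.d. of the multiplicative batch effect.
#' @param dispersion negative-binomial overdispersion (1/size).
#' @param lib_sdlog lognormal s.d. of the per-cell library-size factor.
#' @param kinetics list with \code{beta} and \code{gamma} (meanlog, sdlog of
#'   the per-gene splicing and degradation rates, in 1/pseudotime-segment
#'   units) and \code{step} (integration step).
#' @param acta2_pos_rate,lyz2_pos_rate rates of Acta2-positive macrophages
#'   and Lyz2-positive fibroblasts (double-positive cells).
#' @param seed integer RNG seed.
#' @return A validated list of class \code{CultureConfig}.
#' @export
cultureConfig <- function(n_cells = 8000,
                          population_fractions = .default_population_fractions(),
                          n_genes = 250, marker_log2fc = 10,
                          doublet_rate = 0.01, n_batches = 3,
                          batch_sd = 0.1, dispersion = 0.1,
                          lib_sdlog = 0.3,
                          kinetics = list(beta = c(log(80), 0.2),
                                          gamma = c(log(40), 0.25),
                                          ramp = 0.05, step = 0.01),
                          acta2_pos_rate = 0.05, lyz2_pos_rate = 0.01,
                          seed = 0) {
    pops <- .culture_populations
    if (!setequal(names(population_fractions), pops))
        stop("population_fractions must be named over ",
             paste(pops, collapse = ", "))
    population_fractions <- population_fractions[pops]
    if (abs(sum(population_fractions) - 1) > 1e-8)
        stop("population_fractions must sum to 1")
    named <- unique(c(unlist(.culture_unique_markers), .culture_program_genes()))
    if (n_genes < length(named) + 5)
        stop("n_genes too small for the named marker genes (need >= ",
             length(named) + 5, ")")
    structure(list(n_cells = n_cells,
                   population_fractions = population_fractions,
                   n_genes = n_genes, marker_log2fc = marker_log2fc,
                   doublet_rate = doublet_rate, n_batches = n_batches,
                   batch_sd = batch_sd, dispersion = dispersion,
                   lib_sdlog = lib_sdlog, kinetics = kinetics,
                   acta2_pos_rate = acta2_pos_rate,
                   lyz2_pos_rate = lyz2_pos_rate, seed = seed),
              class = c("CultureConfig", "list"))
}

## All named (non-background, non-unique-marker) genes of the generator.
.culture_program_genes <- function() {
    c(humanMouseMap()$mouse,                       # 12 signature orthologs
      "Acta2", "Tagln", "Myl9", "Vim", "Rhoa",     # contractile program
      "Lox", "Serpinh1", "Sparc", "Col5a2", "Serpine1", "Fn1", "Adamts4",
      "Lyz2", "Csf1r", "Adgre1", "Cd68",           # macrophage program
      "Tgfb2", "Tgfb3",
      "Des", "Smtn", "Myh11", "Cspg4",             # absent SMC/pericyte
      "Ccn1", "Tcf21", "Tbx20", "Frzb",            # senescence / resting
      proliferationGenes(),
      unlist(cellCycleGenes(), use.names = FALSE))
}

## Population x gene matrix of log2 multipliers encoding the expression
## programs (ramps along the FB activation axis, macrophage and endothelial
## identities, proliferation in FB4, ...).
.culturePopEffects <- function(genes, marker_log2fc) {
    pops <- .culture_populations
    M <- matrix(0, length(pops), length(genes),
                dimnames = list(pops, genes))
    set_fb <- function(gs, ramp) {
        gs <- intersect(gs, genes)
        M[paste0("FB", 1:6), gs] <<- matrix(ramp, 6, length(gs))
    }
    for (p in pops)
        M[p, intersect(.culture_unique_markers[[p]], genes)] <- marker_log2fc
    ## macrophage identity + Tgfb1 (switch-like except the graded Tgfb1)
    M[c("MP1", "MP2"), "Lyz2"] <- 11
    M[c("MP1", "MP2"), c("Csf1r", "Adgre1", "Cd68")] <- 10
    M[c("MP1", "MP2"), "Tgfb1"] <- 3
    M["MP1", "Ccl2"] <- 1.5
    ## fibroblast TGFb isoforms
    M[paste0("FB", 1:6), c("Tgfb2", "Tgfb3")] <- 2.5
    ## contractile program (high FB1/FB2, fading toward FB6)
    set_fb("Acta2", c(3, 3.5, 0, 0.5, 0, -2))
    set_fb(c("Tagln", "Myl9", "Vim", "Rhoa"), c(2, 2.5, 0.5, 1.2, 0.3, -1))
    ## ECM ramps
    set_fb(c("Col1a1", "Col1a2", "Col3a1"), c(0, 0, 3, 3.4, 3.4, 4))
    set_fb(c("Lox", "Serpinh1", "Sparc"), c(0, 0, 1, 1.8, 2.2, 1.8))
    set_fb(c("Adamts4", "Serpine1", "Col5a2", "Fn1"),
           c(0, 0, 0.5, 0.5, 2.2, 2.5))
    ## signature genes specific to the FB6 end state (switch-like)
    set_fb(c("Col6a1", "Col12a1", "Col14a1", "Col15a1", "Fbn1", "Timp3"),
           c(0, 0, 0, 0, 0, 10))
    set_fb("Ace2", c(1.5, 1.5, 1.5, 1.5, 1.5, 0))
    set_fb("Ccl2", c(0, 0, 0, 2.5, 0, 0))
    ## senescence / resting programs
    set_fb("Ccn1", c(0, 0, 0, 1, 2, 3))
    set_fb(c("Tcf21", "Tbx20", "Frzb"), c(0, 0, 0, 7, 7, 7))
    ## proliferation: FB4 strongly cycling, FB2/FB5/FB6 moderately,
    ## Ccnd1/Ccnd2 peak in FB1 (all switch-like)
    cc <- cellCycleGenes()
    set_fb(c("Ccnd1", "Ccnd2"), c(8, 6, 0, 7, 0, 0))
    set_fb(setdiff(cc$S, c("Ccnd1", "Ccnd2")), c(0, 7, 0, 7, 6, 6))
    set_fb(cc$G2M, c(0, 7, 0, 8, 6, 6))
    M
}

## Switch-like genes: near-absent off state, strong on state (cell-identity
## markers, cell-cycle genes, FB6-restricted signature genes). All other
## named genes are graded programs on a high baseline.
.culture_switch_genes <- function() {
    cc <- cellCycleGenes()
    unique(c(unlist(.culture_unique_markers, use.names = FALSE),
             "Lyz2", "Csf1r", "Adgre1", "Cd68",
             "Col6a1", "Col12a1", "Col14a1", "Col15a1", "Fbn1", "Timp3",
             "Tcf21", "Tbx20", "Frzb",
             "Des", "Smtn", "Myh11", "Cspg4",
             proliferationGenes(), cc$S, cc$G2M))
}

## Lineage paths (population sequences); FB2 is the root segment.
.culture_paths <- list(
    FB1 = c("FB2", "FB1"),
    FB3 = c("FB2", "FB3", "FB5", "FB6"),
    FB4 = c("FB2", "FB4", "FB5", "FB6"))

## Integrate the two-state kinetics along one path. alpha(t) plateaus at
## each population's program and ramps linearly between programs in a
## window of half-width `ramp` around segment boundaries, starting from a
## quiescent baseline at t = 0. Returns u and s matrices (genes x grid
## points) plus the grid.
.integratePath <- function(path, M, base, beta, gamma, step, ramp = 0.15) {
    K <- length(path)
    grid <- seq(0, K, by = step)
    ## knots: the root segment ramps from the quiescent state across its
    ## whole span (freshly plated cells are still activating); later
    ## segments plateau on [k-1+ramp, k-ramp] with short boundary ramps
    knot_t <- c(0, 1 - ramp,
                if (K > 1) as.vector(rbind(seq(2, K) - 1 + ramp,
                                           seq(2, K) - ramp)))
    G <- length(base)
    rows <- c(1, if (K > 1) rep(seq(2, K), each = 2))
    m_knots <- rbind(0, M[path, , drop = FALSE][rows, , drop = FALSE])
    mt <- apply(m_knots, 2, function(v)
        stats::approx(knot_t, v, xout = grid, rule = 2)$y)  # grid x G
    u <- base * gamma / beta                            # quiescent steady state
    s <- base
    U <- S <- matrix(0, G, length(grid))
    U[, 1] <- u; S[, 1] <- s
    eb <- exp(-beta * step); eg <- exp(-gamma * step)
    for (i in seq_along(grid)[-1]) {
        a <- gamma * base * 2^((mt[i - 1, ] + mt[i, ]) / 2)
        u_new <- a / beta + (u - a / beta) * eb
        s <- s * eg + (a / gamma) * (1 - eg) +
            (beta * u - a) * (eb - eg) / (gamma - beta)
        u <- u_new
        U[, i] <- u; S[, i] <- s
    }
    list(grid = grid, U = U, S = S)
}

#' Generate a synthetic cell-culture scRNA-seq dataset
#'
#' Spliced/unspliced expected values come from two-state kinetics (du/dt =
#' alpha - beta u, ds/dt = beta u - gamma s) integrated along each cell's
#' lineage path with transcription rates ramping between population
#' programs; macrophage and endothelial populations sit at their own steady
#' states. Counts are negative binomial with per-cell library factors and
#' mild per-batch gene-wise effects. Ground truth (population, pseudotime,
#' doublet flags, double-positive flags) is recorded in \code{colData}.
#'
#' @param config A \code{\link{cultureConfig}}.
#' @return An \linkS4class{SCCultureData}; generator truth in
#'   \code{colData()}, kinetic parameters in \code{rowData()}, the
#'   population program matrix in \code{metadata()$pop_log2fc}.
#' @export
generateCultureData <- function(config = cultureConfig()) {
    stopifnot(inherits(config, "CultureConfig"))
    set.seed(config$seed)
    pops <- .culture_populations
    named <- unique(c(unlist(.culture_unique_markers),
                      .culture_program_genes()))
    n_bg <- config$n_genes - length(named)
    genes <- c(named, sprintf("Gm%04d", seq_len(n_bg)))
    G <- length(genes)

    M <- .culturePopEffects(genes, config$marker_log2fc)
    ## switch genes: near-zero off state; graded program genes: high
    ## baseline; background genes: moderate
    is_switch <- genes %in% .culture_switch_genes()
    base <- ifelse(is_switch, stats::rlnorm(G, log(0.01), 0.3),
                   c(stats::rlnorm(length(named), log(15), 0.6),
                     stats::rlnorm(n_bg, log(3), 0.8)))
    beta <- stats::rlnorm(G, config$kinetics$beta[1], config$kinetics$beta[2])
    gamma <- stats::rlnorm(G, config$kinetics$gamma[1],
                           config$kinetics$gamma[2])
    names(base) <- names(beta) <- names(gamma) <- genes

    ## --- cell table ------------------------------------------------------
    n <- config$n_cells
    sizes <- largestRemainder(n, config$population_fractions)
    population <- rep(names(sizes), sizes)
    cell_ids <- sprintf("cell%05d", seq_len(n))

    ## lineage path and pseudotime for fibroblasts
    frac <- config$population_fractions
    w_fb2 <- c(FB1 = unname(frac["FB1"]),
               FB3 = unname(frac["FB3"] + (frac["FB5"] + frac["FB6"]) / 2),
               FB4 = unname(frac["FB4"] + (frac["FB5"] + frac["FB6"]) / 2))
    path <- rep(NA_character_, n)
    ptime <- rep(NA_real_, n)
    for (p in setdiff(pops, c("EC", "MP1", "MP2"))) {
        idx <- which(population == p)
        path[idx] <- switch(p,
            FB2 = sample(names(w_fb2), length(idx), TRUE, prob = w_fb2),
            FB1 = "FB1", FB3 = "FB3", FB4 = "FB4",
            sample(c("FB3", "FB4"), length(idx), TRUE))
        seg <- vapply(path[idx], function(pp)
            match(p, .culture_paths[[pp]]), integer(1))
        ptime[idx] <- seg - 1 + stats::runif(length(idx))
    }

    ## --- expected u/s per cell ------------------------------------------
    EU <- ES <- matrix(0, G, n, dimnames = list(genes, cell_ids))
    step <- config$kinetics$step
    for (pn in names(.culture_paths)) {
        idx <- which(path == pn)
        if (!length(idx)) next
        tr <- .integratePath(.culture_paths[[pn]], M, base, beta, gamma,
                             step, config$kinetics$ramp)
        gi <- pmin(1 + round(ptime[idx] / step), length(tr$grid))
        EU[, idx] <- tr$U[, gi]
        ES[, idx] <- tr$S[, gi]
    }
    for (p in c("EC", "MP1", "MP2")) {
        idx <- which(population == p)
        s_star <- base * 2^M[p, ]
        ES[, idx] <- s_star
        EU[, idx] <- s_star * gamma / beta
    }

    ## double positives: Acta2+ macrophages, Lyz2+ fibroblasts
    mp_cells <- which(population %in% c("MP1", "MP2"))
    fb_cells <- which(startsWith(population, "FB"))
    acta2_pos <- rep(FALSE, n)
    lyz2_pos <- rep(FALSE, n)
    acta2_pos[sample(mp_cells, round(config$acta2_pos_rate *
                                     length(mp_cells)))] <- TRUE
    lyz2_pos[sample(fb_cells, round(config$lyz2_pos_rate *
                                    length(fb_cells)))] <- TRUE
    ES["Acta2", acta2_pos] <- ES["Acta2", acta2_pos] * 2^3
    EU["Acta2", acta2_pos] <- EU["Acta2", acta2_pos] * 2^3
    ES["Lyz2", lyz2_pos] <- ES["Lyz2", lyz2_pos] * 2^3
    EU["Lyz2", lyz2_pos] <- EU["Lyz2", lyz2_pos] * 2^3

    ## --- sampling --------------------------------------------------------
    batch <- sample(seq_len(config$n_batches), n, TRUE)
    bfac <- matrix(2^stats::rnorm(config$n_batches * G, 0, config$batch_sd),
                   config$n_batches, G)
    lib <- stats::rlnorm(n, 0, config$lib_sdlog)
    fac <- t(bfac[batch, , drop = FALSE]) *
        matrix(lib, G, n, byrow = TRUE)                 # G x n
    size <- 1 / config$dispersion
    sp <- matrix(stats::rnbinom(G * n, mu = ES * fac, size = size), G, n,
                 dimnames = list(genes, cell_ids))
    un <- matrix(stats::rnbinom(G * n, mu = EU * fac, size = size), G, n,
                 dimnames = list(genes, cell_ids))

    ## --- doublets --------------------------------------------------------
    m <- round(config$doublet_rate * n)
    is_doublet <- rep(FALSE, n)
    if (m > 0) {
        i1 <- sample(n, m, TRUE)
        i2 <- sample(n, m, TRUE)
        shift <- i1 == i2
        i2[shift] <- (i2[shift] %% n) + 1
        dbl_ids <- sprintf("dbl%04d", seq_len(m))
        sp <- cbind(sp, matrix(sp[, i1] + sp[, i2], G, m,
                               dimnames = list(genes, dbl_ids)))
        un <- cbind(un, matrix(un[, i1] + un[, i2], G, m,
                               dimnames = list(genes, dbl_ids)))
        population <- c(population, rep(NA_character_, m))
        batch <- c(batch, batch[i1])
        path <- c(path, rep(NA_character_, m))
        ptime <- c(ptime, rep(NA_real_, m))
        acta2_pos <- c(acta2_pos, rep(FALSE, m))
        lyz2_pos <- c(lyz2_pos, rep(FALSE, m))
        is_doublet <- c(is_doublet, rep(TRUE, m))
    }

    out <- SCCultureData(sp, un, batch = factor(batch),
                         population = population,
                         is_doublet = is_doublet, pseudotime = ptime)
    colData(out)$path <- path
    colData(out)$acta2_pos <- acta2_pos
    colData(out)$lyz2_pos <- lyz2_pos
    rowData(out)$baseline <- base
    rowData(out)$beta <- beta
    rowData(out)$gamma <- gamma
    metadata(out)$pop_log2fc <- M
    metadata(out)$config <- config
    out
}

#' Ground-truth population mean signatures
#'
#' Mean expression (expected spliced level, not counts) of every gene per
#' population at the population's program steady state; used as the mixing
#' signatures of the bulk time-course generator.
#'
#' @param data An \linkS4class{SCCultureData} produced by
#'   \code{\link{generateCultureData}}.
#' @return genes x populations matrix.
#' @export
populationSignatures <- function(data) {
    M <- metadata(data)$pop_log2fc
    if (is.null(M)) stop("no generator truth in metadata(data)")
    base <- rowData(data)$baseline
    sig <- t(2^M) * base
    dimnames(sig) <- list(rownames(data), rownames(M))
    sig
}
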