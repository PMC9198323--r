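## Synthetic bulk time-course generator: each post-infarct stage is a convex
## mixture of fibroblast subpopulation signatures plus stage-invariant
## background genes, with negative-binomial counts.

.default_mixing_weights <- function() {
    w <- rbind(
        uninjured = c(0.05, 0.60, 0.25, 0.02, 0.05, 0.03),
        `3d`      = c(0.03, 0.25, 0.20, 0.35, 0.12, 0.05),
        `7d`      = c(0.03, 0.20, 0.20, 0.05, 0.30, 0.22),
        `2w`      = c(0.03, 0.50, 0.25, 0.05, 0.10, 0.07),
        later     = c(0.03, 0.55, 0.25, 0.03, 0.08, 0.06))
    colnames(w) <- paste0("FB", 1:6)
    w
}

#' Configuration for the synthetic bulk infarct time course
#'
#' Default mixing weights encode the staged fibroblast response: the
#' proliferative FB4 pool peaks at 3 days after infarction, the
#' matrix-producing FB5/FB6 pools peak at 7 days, and composition is close
#' to the uninjured heart again from 2 weeks on; FB2/FB3 contributions are
#' roughly equal at 3d and 7d.
#'
#' @param stages ordered stage labels.
#' @param replicates_per_stage replicates per stage.
#' @param mixing_weights stages x populations matrix of nonnegative weights
#'   (rows are normalized to sum 1).
#' @param n_background_genes stage-invariant background genes appended to
#'   the signature genes.
#' @param dispersion negative-binomial overdispersion (1/size).
#' @param lib_sdlog lognormal s.d. of per-sample depth factors.
#' @param depth target mean total counts per sample.
#' @param seed RNG seed.
#' @return A validated list of class \code{TimecourseConfig}.
#' @export
timecourseConfig <- function(stages = c("uninjured", "3d", "7d", "2w",
                                        "later"),
                             replicates_per_stage = 4,
                             mixing_weights = .default_mixing_weights(),
                             n_background_genes = 400,
                             dispersion = 0.02, lib_sdlog = 0.1,
                             depth = 5e5, seed = 0) {
    if (anyDuplicated(stages)) stop("stage labels must be unique")
    if (!identical(rownames(mixing_weights), as.character(stages)))
        stop("mixing_weights rows must match stages (in order)")
    if (any(mixing_weights < 0)) stop("mixing weights must be nonnegative")
    if (any(rowSums(mixing_weights) == 0))
        stop("each stage needs positive total weight")
    mixing_weights <- mixing_weights / rowSums(mixing_weights)
    structure(list(stages = stages,
                   replicates_per_stage = replicates_per_stage,
                   mixing_weights = mixing_weights,
                   n_background_genes = n_background_genes,
                   dispersion = dispersion, lib_sdlog = lib_sdlog,
                   depth = depth, seed = seed),
              class = c("TimecourseConfig", "list"))
}

#' Generate a synthetic bulk time course
#'
#' Each sample's expected expression is its stage's convex mixture of the
#' supplied population signatures plus stage-invariant background genes;
#' counts are negative binomial at the configured dispersion and depth.
#'
#' @param config A \code{\link{timecourseConfig}}.
#' @param signatures genes x populations mean-expression matrix covering all
#'   populations named in the mixing weights (e.g.
#'   \code{\link{populationSignatures}} of a synthetic culture).
#' @return A \linkS4class{BulkTimecourse}; \code{rowData()} records each
#'   gene's expected per-stage expression range on the log2 scale
#'   (\code{true_log2_range}) — genes with range > 0.5 are the planted
#'   stage-varying set.
#' @export
generateBulkTimecourse <- function(config = timecourseConfig(), signatures) {
    stopifnot(inherits(config, "TimecourseConfig"))
    w <- config$mixing_weights
    missing <- setdiff(colnames(w), colnames(signatures))
    if (length(missing))
        stop("signatures missing populations: ",
             paste(missing, collapse = ", "))
    set.seed(config$seed)

    sig <- signatures[, colnames(w), drop = FALSE]
    expected_sig <- sig %*% t(w)                  # genes x stages
    n_bg <- config$n_background_genes
    bg <- matrix(stats::rlnorm(n_bg, log(3), 0.8), n_bg, nrow(w),
                 dimnames = list(sprintf("Bg%04d", seq_len(n_bg)),
                                 rownames(w)))
    expected <- rbind(expected_sig, bg)

    stages <- rep(config$stages, each = config$replicates_per_stage)
    ids <- paste0(stages, "_r",
                  rep(seq_len(config$replicates_per_stage),
                      times = length(config$stages)))
    mu <- expected[, stages, drop = FALSE]
    sf <- config$depth / mean(colSums(mu))
    mu <- mu * sf * matrix(stats::rlnorm(length(stages), 0,
                                         config$lib_sdlog),
                           nrow(mu), length(stages), byrow = TRUE)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$dispersion),
                     nrow(mu), ncol(mu),
                     dimnames = list(rownames(expected), ids))

    lr <- apply(log2(expected + 0.5), 1, function(x) max(x) - min(x))
    BulkTimecourse(counts, stage = stages,
                   rowData = data.frame(true_log2_range = lr))
}
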