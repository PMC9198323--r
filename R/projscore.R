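## Projection score: informativeness of a gene subset's low-dimensional
## principal-component projection, relative to random subsets of the same
## size. Used to pick the optimal variance-filter level for the fibrosis
## signature.

#' Alpha score of a gene subset
#'
#' Column-standardizes the samples x genes submatrix and returns
#' alpha = sqrt(sum of the d leading eigenvalues / sum of all eigenvalues)
#' of its covariance — the fraction of variance captured by a d-dimensional
#' projection, on the singular-value scale.
#'
#' @param matrix samples x genes numeric matrix.
#' @param subset gene ids (columns) to score.
#' @param d projection dimension.
#' @return alpha in [0, 1].
#' @export
alphaScore <- function(matrix, subset, d = 2) {
    stopifnot(length(subset) >= 1)
    x <- matrix[, subset, drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance gene(s) in subset: ",
             paste(colnames(x)[sds == 0], collapse = ", "))
    x <- scale(x)
    ev <- svd(x, nu = 0, nv = 0)$d^2
    sqrt(sum(ev[seq_len(min(d, length(ev)))]) / sum(ev))
}

#' Projection score of a gene subset
#'
#' tau = alpha(subset) minus the mean alpha of B random gene subsets of the
#' same size drawn uniformly from the full gene universe of the matrix.
#' Positive tau means the subset's low-dimensional structure exceeds what
#' same-sized random subsets capture.
#'
#' @inheritParams alphaScore
#' @param B number of random subsets (>= 10).
#' @param seed RNG seed for the null draws.
#' @return List with \code{tau}, \code{alpha}, \code{alpha_random_mean},
#'   \code{alpha_random_sd} (spread of the null alphas — the scale against
#'   which an observed tau must be judged) and \code{alpha_random_se}
#'   (Monte-Carlo standard error of their mean).
#' @export
projectionScore <- function(matrix, subset, d = 2, B = 100, seed = 0) {
    if (B < 10) stop("B must be >= 10")
    a_obs <- alphaScore(matrix, subset, d)
    genes <- colnames(matrix)
    set.seed(seed)
    a_rand <- vapply(seq_len(B), function(b)
        alphaScore(matrix, sample(genes, length(subset)), d), numeric(1))
    list(tau = a_obs - mean(a_rand), alpha = a_obs,
         alpha_random_mean = mean(a_rand),
         alpha_random_sd = stats::sd(a_rand),
         alpha_random_se = stats::sd(a_rand) / sqrt(B))
}

#' Select the optimal variance-filtered gene subset by projection score
#'
#' Scans variance-filter thresholds; at each, takes the genes above that
#' variance quantile and computes tau. Returns the threshold/subset with
#' maximal tau (ties broken toward the larger subset, then the lower
#' threshold). When even the best tau is within twice the null spread of
#' alpha (the s.d. of the random-subset alphas) the result is flagged as
#' having no informative subset: under a pure-noise matrix the observed
#' alpha is itself one draw from that null.
#'
#' @param matrix samples x genes numeric matrix (e.g. transposed normalized
#'   panel values restricted to fibroblast genes).
#' @param d projection dimension.
#' @param B random subsets per threshold.
#' @param thresholds variance-filter levels to scan.
#' @param seed RNG seed.
#' @return List of class \code{ProjectionScoreResult}: \code{trace} (per
#'   threshold: size, alpha, alpha_random_mean, tau), \code{best_threshold},
#'   \code{best_subset}, \code{best_tau}, \code{informative}.
#' @export
selectOptimalSubset <- function(matrix, d = 2, B = 100,
                                thresholds = seq(0.5, 0.95, by = 0.05),
                                seed = 0) {
    if (!length(thresholds)) stop("thresholds must be nonempty")
    v <- apply(matrix, 2, stats::var)
    rows <- list(); subsets <- list()
    for (th in thresholds) {
        keep <- colnames(matrix)[v >= stats::quantile(v, th)]
        if (!length(keep)) {
            message("threshold ", th, " yields an empty subset; skipped")
            next
        }
        ps <- projectionScore(matrix, keep, d = d, B = B,
                              seed = childSeed(seed, sprintf("th%.3f", th)))
        rows[[length(rows) + 1L]] <- data.frame(
            threshold = th, size = length(keep), alpha = ps$alpha,
            alpha_random_mean = ps$alpha_random_mean, tau = ps$tau,
            null_sd = ps$alpha_random_sd)
        subsets[[length(subsets) + 1L]] <- keep
    }
    if (!length(rows)) stop("all thresholds yielded empty subsets")
    trace <- do.call(rbind, rows)
    ## argmax tau; ties -> larger subset, then lower threshold
    best <- order(-trace$tau, -trace$size, trace$threshold)[1]
    structure(list(trace = trace,
                   best_threshold = trace$threshold[best],
                   best_subset = sort(subsets[[best]]),
                   best_tau = trace$tau[best],
                   informative = trace$tau[best] >= 2 * trace$null_sd[best]),
              class = "ProjectionScoreResult")
}

#' @export
print.ProjectionScoreResult <- function(x, ...) {
    cat("Projection-score threshold scan\n")
    print(x$trace, row.names = FALSE, digits = 4)
    cat(sprintf("best threshold %.2f: %d genes, tau = %.4f%s\n",
                x$best_threshold, length(x$best_subset), x$best_tau,
                if (x$informative) "" else " (no informative subset)"))
    invisible(x)
}
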