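## Steady-state RNA velocity: per-gene degradation-ratio fit on kNN-smoothed
## spliced/unspliced counts, per-cell velocity vectors v = u - gamma*s, a
## velocity graph of edge-wise cosine correlations, and projection of the
## velocities onto a 2-D embedding.

#' kNN smoothing of the count layers
#'
#' First-order neighbour averaging: each cell's spliced and unspliced
#' vectors are replaced by the mean over itself and its k nearest
#' neighbours in PC space.
#'
#' @param data A preprocessed \linkS4class{SCCultureData}.
#' @param k neighbours for smoothing (default 30).
#' @return The object with assays \code{Ms} and \code{Mu} (smoothed layers).
#' @export
smoothCounts <- function(data, k = 30) {
    pca <- SingleCellExperiment::reducedDim(data, "PCA")
    nn <- if (!is.null(metadata(data)$knn) &&
              ncol(metadata(data)$knn) == k) metadata(data)$knn
          else knnIndices(pca, k)
    n <- ncol(data)
    ## sparse averaging operator over {self, neighbours}
    A <- Matrix::sparseMatrix(
        i = c(seq_len(n), rep(seq_len(n), ncol(nn))),
        j = c(seq_len(n), as.vector(nn)),
        x = 1 / (ncol(nn) + 1), dims = c(n, n))
    Ms <- as.matrix(Matrix::tcrossprod(spliced(data), A))
    Mu <- as.matrix(Matrix::tcrossprod(unspliced(data), A))
    dimnames(Ms) <- dimnames(Mu) <- dimnames(data)
    assay(data, "Ms") <- Ms
    assay(data, "Mu") <- Mu
    data
}

#' Fit per-gene steady-state ratios
#'
#' For each gene, gamma is the regression-through-the-origin slope
#' sum(u_i s_i) / sum(s_i^2) over the extreme cells — the union of the top
#' and bottom q-quantiles of the smoothed spliced values. Genes whose
#' spliced values are all zero are flagged unfitted.
#'
#' @param data An \linkS4class{SCCultureData} with smoothed layers (see
#'   \code{\link{smoothCounts}}).
#' @param q extreme-quantile fraction (default 0.05).
#' @param min_extreme minimum number of extreme cells per gene.
#' @return List of class \code{VelocityModel}: \code{gamma} (per gene, NA
#'   when unfitted), \code{fitted} (logical), \code{q}, and the per-gene
#'   residual s.d. over the extreme set.
#' @export
fitGamma <- function(data, q = 0.05, min_extreme = 4) {
    stopifnot(all(c("Ms", "Mu") %in% assayNames(data)))
    S <- assay(data, "Ms"); U <- assay(data, "Mu")
    n <- ncol(S)
    gamma <- rep(NA_real_, nrow(S))
    resid_sd <- rep(NA_real_, nrow(S))
    names(gamma) <- names(resid_sd) <- rownames(S)
    for (g in seq_len(nrow(S))) {
        s <- S[g, ]; u <- U[g, ]
        if (all(s == 0)) next
        lo <- stats::quantile(s, q); hi <- stats::quantile(s, 1 - q)
        ext <- which(s <= lo | s >= hi)
        if (length(ext) < min_extreme) ext <- seq_len(n)
        denom <- sum(s[ext]^2)
        if (denom == 0) next
        gamma[g] <- sum(u[ext] * s[ext]) / denom
        resid_sd[g] <- stats::sd(u[ext] - gamma[g] * s[ext])
    }
    structure(list(gamma = gamma, fitted = !is.na(gamma), q = q,
                   resid_sd = resid_sd),
              class = "VelocityModel")
}

#' @export
print.VelocityModel <- function(x, ...) {
    cat("VelocityModel:", sum(x$fitted), "of", length(x$gamma),
        "genes fitted (q =", x$q, ")\n")
    cat("  gamma quartiles:",
        paste(signif(stats::quantile(x$gamma, c(0.25, 0.5, 0.75),
                                     na.rm = TRUE), 3), collapse = " "),
        "\n")
    invisible(x)
}

#' Per-cell velocity vectors
#'
#' v = u - gamma * s elementwise over the fitted genes, on the smoothed
#' layers.
#'
#' @param data An \linkS4class{SCCultureData} with smoothed layers.
#' @param model A \code{\link{fitGamma}} result.
#' @return genes x cells matrix of velocities (fitted genes only).
#' @export
computeVelocity <- function(data, model) {
    stopifnot(inherits(model, "VelocityModel"))
    keep <- model$fitted
    assay(data, "Mu")[keep, , drop = FALSE] -
        model$gamma[keep] * assay(data, "Ms")[keep, , drop = FALSE]
}

#' Velocity graph: edge cosine correlations
#'
#' For each directed kNN edge i -> j, the cosine similarity between cell
#' i's velocity vector and the displacement x_j - x_i in log1p expression
#' space of the fitted genes. Zero-velocity cells get 0 on all their edges.
#'
#' @param data An \linkS4class{SCCultureData} with smoothed layers and kNN
#'   graph.
#' @param velocity genes x cells velocity matrix from
#'   \code{\link{computeVelocity}}.
#' @return List of class \code{VelocityGraph}: \code{nn} (n x k neighbour
#'   indices) and \code{cos} (n x k edge cosine values in [-1, 1]).
#' @export
velocityGraph <- function(data, velocity) {
    nn <- metadata(data)$knn
    if (is.null(nn)) stop("no kNN graph; run preprocessCells() first")
    x <- t(log1p(assay(data, "Ms")[rownames(velocity), , drop = FALSE]))
    v <- t(velocity)                     # cells x genes
    n <- nrow(x); k <- ncol(nn)
    cosm <- matrix(0, n, k)
    vn <- sqrt(rowSums(v^2))
    for (i in seq_len(n)) {
        if (vn[i] == 0) next
        d <- x[nn[i, ], , drop = FALSE] -
            matrix(x[i, ], k, ncol(x), byrow = TRUE)
        dn <- sqrt(rowSums(d^2))
        ok <- dn > 0
        cosm[i, ok] <- (d[ok, , drop = FALSE] %*% v[i, ]) /
            (dn[ok] * vn[i])
    }
    structure(list(nn = nn, cos = cosm), class = "VelocityGraph")
}

#' Project velocities onto a 2-D embedding
#'
#' Transition probabilities over each cell's neighbours are a softmax of the
#' edge cosines (temperature sigma); the cell's arrow is the
#' probability-weighted mean displacement minus the uniform-weight mean:
#' arrow_i = sum_j (pi_ij - 1/k)(e_j - e_i). Cells with no informative edges
#' get a zero arrow.
#'
#' @param graph A \code{\link{velocityGraph}} result.
#' @param embedding cells x 2 coordinate matrix.
#' @param sigma softmax temperature (default 0.1).
#' @return cells x 2 matrix of arrows.
#' @export
embedVelocity <- function(graph, embedding, sigma = 0.1) {
    stopifnot(inherits(graph, "VelocityGraph"))
    nn <- graph$nn; cosm <- graph$cos
    n <- nrow(nn); k <- ncol(nn)
    arrows <- matrix(0, n, 2,
                     dimnames = list(rownames(embedding), c("dx", "dy")))
    for (i in seq_len(n)) {
        w <- exp(cosm[i, ] / sigma)
        w <- w / sum(w)
        delta <- embedding[nn[i, ], , drop = FALSE] -
            matrix(embedding[i, ], k, 2, byrow = TRUE)
        arrows[i, ] <- colSums((w - 1 / k) * delta)
    }
    arrows
}
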