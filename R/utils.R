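## Shared numeric helpers.

## Largest-remainder rounding of n * fractions to integers summing to n.
## Ties in the remainders are broken by name order (then position).
largestRemainder <- function(n, fractions) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    raw <- n * fractions
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        rem <- raw - base
        nm <- if (is.null(names(fractions))) as.character(seq_along(fractions))
              else names(fractions)
        ord <- order(-rem, nm)
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    stats::setNames(as.integer(base), names(fractions))
}

## Vectorised Welch two-sample t over the rows of x (rows = genes).
## Returns t, df, p (two-sided). Rows with zero variance in both groups get
## NA and are reported via the 'skipped' attribute.
rowWelchT <- function(x, in_a, in_b) {
    xa <- x[, in_a, drop = FALSE]
    xb <- x[, in_b, drop = FALSE]
    na <- ncol(xa); nb <- ncol(xb)
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2) / (na - 1)
    vb <- rowSums((xb - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    bad <- se2 == 0
    t[bad] <- NA_real_; df[bad] <- NA_real_
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    res <- data.frame(t = t, df = df, p = p, mean_diff = ma - mb,
                      row.names = rownames(x))
    attr(res, "skipped") <- rownames(x)[bad]
    res
}

## Vectorised one-way ANOVA F over rows of x; g is the grouping factor.
rowAnovaF <- function(x, g) {
    g <- droplevels(factor(g))
    k <- nlevels(g); n <- ncol(x)
    stopifnot(k >= 2, n > k)
    gm <- rowMeans(x)
    ssb <- 0; ssw <- 0
    for (lev in levels(g)) {
        idx <- which(g == lev)
        xg <- x[, idx, drop = FALSE]
        mg <- rowMeans(xg)
        ssb <- ssb + length(idx) * (mg - gm)^2
        ssw <- ssw + rowSums((xg - mg)^2)
    }
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    f <- msb / msw
    p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
    ## degenerate rows: no within-group variance
    degen <- msw == 0
    p[degen & msb == 0] <- 1        # flat gene: no evidence either way
    p[degen & msb > 0] <- 0
    data.frame(F = f, p = p, row.names = rownames(x))
}

## z-score rows of a matrix; denom = "sample" (n-1) or "population" (n).
rowZscore <- function(x, denom = c("sample", "population")) {
    denom <- match.arg(denom)
    mu <- rowMeans(x)
    n <- ncol(x)
    ss <- rowSums((x - mu)^2)
    sd <- sqrt(ss / if (denom == "sample") n - 1 else n)
    z <- (x - mu) / sd
    z[sd == 0, ] <- 0
    z
}

## Exact kNN in a coordinate matrix (rows = points). Returns an index matrix
## (n x k) of neighbours, self excluded. Thin wrapper over BiocNeighbors.
knnIndices <- function(coords, k) {
    stopifnot(k < nrow(coords))
    ## tied distances are routine with discrete counts; the warning is noise
    res <- withCallingHandlers(
        BiocNeighbors::findKNN(coords, k = k,
                               BNPARAM = BiocNeighbors::KmknnParam()),
        warning = function(w) {
            if (grepl("tied distances", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    res$index
}

## Derive a reproducible child seed from a base seed and a stream label.
childSeed <- function(seed, stream) {
    (seed * 48271 + sum(utf8ToInt(stream)) * 7919) %% 2147483647
}
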