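## Signature matching: per-group z-scored profiles over a gene set, and
## Pearson matching of the patient signature to fibroblast subpopulations
## across species.

#' Per-group z-scored signature profile
#'
#' For each gene of the set: group means of the expression values, then a
#' z-score across groups (population/n denominator, for exact
#' reproducibility). Genes constant across groups are flagged and their rows
#' set to zero; they are excluded from correlations.
#'
#' @param expression genes x samples/cells matrix (normalized values).
#' @param gene_set ordered gene set; if \code{species_map} is given, names
#'   are translated before lookup.
#' @param group_labels per-column group labels (>= 2 groups).
#' @param species species tag stored on the profile.
#' @param species_map optional two-column data.frame mapping the supplied
#'   gene names to the expression rownames (e.g.
#'   \code{\link{humanMouseMap}}); unmapped genes are an error.
#' @return A \linkS4class{SignatureProfile} (rows keep the supplied gene
#'   names and order).
#' @export
groupProfile <- function(expression, gene_set, group_labels,
                         species = "unknown", species_map = NULL) {
    lookup <- gene_set
    if (!is.null(species_map)) {
        idx <- match(gene_set, species_map[[1]])
        if (anyNA(idx))
            stop("unmapped gene(s): ",
                 paste(gene_set[is.na(idx)], collapse = ", "))
        lookup <- species_map[[2]][idx]
    }
    missing <- setdiff(lookup, rownames(expression))
    if (length(missing))
        stop("gene(s) absent from expression: ",
             paste(missing, collapse = ", "))
    groups <- factor(group_labels)
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    x <- expression[lookup, , drop = FALSE]
    means <- vapply(levels(groups), function(g)
        rowMeans(x[, groups == g, drop = FALSE]), numeric(length(lookup)))
    if (length(lookup) == 1L)
        means <- matrix(means, 1, dimnames = list(lookup, levels(groups)))
    mu <- rowMeans(means)
    sd <- sqrt(rowSums((means - mu)^2) / ncol(means))   # population s.d.
    constant <- sd == 0
    z <- (means - mu) / ifelse(sd == 0, 1, sd)
    z[constant, ] <- 0
    rownames(z) <- gene_set
    new("SignatureProfile", values = z, constant = constant,
        species = species)
}

#' Match a signature profile against subpopulation profiles
#'
#' Pearson correlation between one group's z-score vector of profile a and
#' each group (subpopulation) vector of profile b, over the shared usable
#' (non-constant) genes. Reports all correlations, which subpopulations are
#' positive, and the best match.
#'
#' @param profile_a A \linkS4class{SignatureProfile} (e.g. the HF patient
#'   profile).
#' @param profiles_b A \linkS4class{SignatureProfile} whose groups are the
#'   subpopulations to match against.
#' @param target_group column of \code{profile_a} to match (default: last
#'   group, e.g. the severe-fibrosis cluster).
#' @return data.frame with \code{population}, \code{r}, \code{positive},
#'   \code{best}; attribute \code{genes_used}.
#' @export
matchSignature <- function(profile_a, profiles_b,
                           target_group = ncol(profileValues(profile_a))) {
    a <- profileValues(profile_a)
    b <- profileValues(profiles_b)
    shared <- intersect(rownames(a), rownames(b))
    usable <- shared[!(profile_a@constant[match(shared, rownames(a))] |
                       profiles_b@constant[match(shared, rownames(b))])]
    if (length(usable) < 3)
        stop("fewer than 3 usable shared genes")
    av <- a[usable, target_group]
    rs <- apply(b[usable, , drop = FALSE], 2,
                function(bv) stats::cor(av, bv))
    out <- data.frame(population = colnames(b), r = rs,
                      positive = rs > 0,
                      best = seq_along(rs) == which.max(rs))
    attr(out, "genes_used") <- usable
    out
}
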