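#' @import methods
#' @import SummarizedExperiment
#' @import SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' PanelCohort: targeted expression panel of a patient cohort
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are panel genes (plus the
#' reference genes, flagged in \code{rowData()$is_reference}), columns are
#' samples. The \code{counts} assay holds nonnegative integer counts;
#' \code{colData} carries \code{group} ("donor"/"HF"), \code{age} and
#' clinical flags (\code{ischemic}, \code{diabetes}, \code{high_bmi},
#' \code{female}), optionally a ground-truth \code{true_subcluster}.
#'
#' @export
setClass("PanelCohort", contains = "SummarizedExperiment")

setValidity("PanelCohort", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    cd <- colData(object)
    if (!all(c("group", "age") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'age'")
    else {
        if (!all(cd$group %in% c("donor", "HF")))
            msg <- c(msg, "group must be 'donor' or 'HF'")
        if (any(cd$age <= 0)) msg <- c(msg, "ages must be positive")
    }
    if (!"is_reference" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must flag reference genes ('is_reference')")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PanelCohort
#'
#' @param counts genes x samples nonnegative integer matrix with dimnames.
#' @param group character vector ("donor"/"HF") per sample.
#' @param age numeric ages (years) per sample.
#' @param ref_genes character; reference gene ids (must be rows of counts).
#' @param flags optional data.frame of per-sample logical clinical flags.
#' @param true_subcluster optional integer ground-truth subcluster (NA for
#'   donors and unassigned samples).
#' @param rowData optional extra per-gene annotation.
#' @return A \linkS4class{PanelCohort}.
#' @export
PanelCohort <- function(counts, group, age,
                        ref_genes = panelReferenceGenes(),
                        flags = NULL, true_subcluster = NULL,
                        rowData = NULL) {
    if (!all(ref_genes %in% rownames(counts)))
        stop("reference genes missing from counts: ",
             paste(setdiff(ref_genes, rownames(counts)), collapse = ", "))
    cd <- DataFrame(group = group, age = age, row.names = colnames(counts))
    if (!is.null(flags)) cd <- cbind(cd, DataFrame(flags))
    if (!is.null(true_subcluster)) cd$true_subcluster <- true_subcluster
    rd <- DataFrame(is_reference = rownames(counts) %in% ref_genes,
                    row.names = rownames(counts))
    if (!is.null(rowData)) rd <- cbind(rd, DataFrame(rowData))
    new("PanelCohort",
        SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd))
}

#' SCCultureData: spliced/unspliced single-cell counts of a cell culture
#'
#' Extends \linkS4class{SingleCellExperiment}. Rows are genes, columns cells.
#' Assays \code{spliced} and \code{unspliced} hold the two count layers;
#' \code{colData} carries \code{batch} and, for synthetic data, the
#' ground-truth \code{population} and \code{is_doublet}. Derived layers
#' (\code{logcounts}, PCA, kNN graph, clusters, embedding) are added by the
#' processing functions.
#'
#' @export
setClass("SCCultureData", contains = "SingleCellExperiment")

setValidity("SCCultureData", function(object) {
    msg <- NULL
    if (!all(c("spliced", "unspliced") %in% assayNames(object)))
        msg <- c(msg, "assays 'spliced' and 'unspliced' are required")
    else if (any(assay(object, "spliced") < 0) ||
             any(assay(object, "unspliced") < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (!"batch" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'batch'")
    if (is.null(msg)) TRUE else msg
})

#' Construct an SCCultureData
#'
#' @param spliced,unspliced genes x cells nonnegative count matrices with
#'   identical dimnames.
#' @param batch per-cell batch labels.
#' @param population optional ground-truth population labels.
#' @param is_doublet optional logical ground-truth doublet flags.
#' @param pseudotime optional ground-truth pseudotime.
#' @return An \linkS4class{SCCultureData}.
#' @export
SCCultureData <- function(spliced, unspliced, batch,
                          population = NULL, is_doublet = NULL,
                          pseudotime = NULL) {
    stopifnot(identical(dim(spliced), dim(unspliced)),
              identical(dimnames(spliced), dimnames(unspliced)))
    cd <- DataFrame(batch = batch, row.names = colnames(spliced))
    if (!is.null(population)) cd$population <- population
    if (!is.null(is_doublet)) cd$is_doublet <- is_doublet
    if (!is.null(pseudotime)) cd$pseudotime <- pseudotime
    new("SCCultureData",
        SingleCellExperiment(
            assays = list(spliced = spliced, unspliced = unspliced),
            colData = cd))
}

#' BulkTimecourse: staged bulk expression
#'
#' Extends \linkS4class{SummarizedExperiment}; rows genes, columns samples.
#' \code{colData$stage} is an ordered factor; \code{colData$replicate}
#' numbers replicates within stage.
#'
#' @export
setClass("BulkTimecourse", contains = "SummarizedExperiment")

setValidity("BulkTimecourse", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    if (!"stage" %in% colnames(cd))
        msg <- c(msg, "colData must contain 'stage'")
    else if (length(unique(cd$stage)) < 2)
        msg <- c(msg, "at least 2 stages are required")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BulkTimecourse
#'
#' @param counts genes x samples nonnegative matrix.
#' @param stage per-sample stage labels; order of first appearance (or factor
#'   levels) defines the stage ordering.
#' @param replicate optional replicate ids.
#' @param rowData optional per-gene annotation.
#' @return A \linkS4class{BulkTimecourse}.
#' @export
BulkTimecourse <- function(counts, stage, replicate = NULL, rowData = NULL) {
    if (!is.factor(stage)) stage <- factor(stage, levels = unique(stage))
    stage <- factor(stage, levels = levels(stage), ordered = TRUE)
    cd <- DataFrame(stage = stage, row.names = colnames(counts))
    cd$replicate <- if (is.null(replicate))
        as.integer(stats::ave(seq_along(stage), stage, FUN = seq_along))
    else replicate
    rd <- if (is.null(rowData)) NULL else DataFrame(rowData)
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    if (!is.null(rd)) rowData(se) <- cbind(rowData(se), rd)
    new("BulkTimecourse", se)
}

#' CellTypeReference: mean expression of panel genes per cell type
#'
#' Holds a genes x cell-types matrix of mean expression and a grouping map
#' assigning each reference cell type to one of the pooled groups
#' "cardiomyocyte", "fibroblast_pericyte" or "other", which drive the
#' gene-category assignment rule.
#'
#' @slot means genes x cell types nonnegative matrix.
#' @slot typeGroups named character; for each cell type (column of
#'   \code{means}) its pooled group.
#' @export
setClass("CellTypeReference",
         representation(means = "matrix", typeGroups = "character"))

setValidity("CellTypeReference", function(object) {
    msg <- NULL
    if (any(object@means < 0)) msg <- c(msg, "negative reference values")
    if (!identical(sort(colnames(object@means)),
                   sort(names(object@typeGroups))))
        msg <- c(msg, "typeGroups must name every cell type")
    if (!all(object@typeGroups %in%
             c("cardiomyocyte", "fibroblast_pericyte", "other")))
        msg <- c(msg, "typeGroups values must be cardiomyocyte, ",
                 "fibroblast_pericyte or other")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CellTypeReference
#'
#' @param means genes x cell-types nonnegative matrix with dimnames.
#' @param typeGroups named character vector mapping each cell type to
#'   "cardiomyocyte", "fibroblast_pericyte" or "other".
#' @return A \linkS4class{CellTypeReference}.
#' @export
CellTypeReference <- function(means, typeGroups) {
    new("CellTypeReference", means = means, typeGroups = typeGroups)
}

setMethod("show", "CellTypeReference", function(object) {
    cat("CellTypeReference:", nrow(object@means), "genes x",
        ncol(object@means), "cell types\n")
    cat("  groups:", paste(sprintf("%s(%d)",
        unique(object@typeGroups),
        as.vector(table(object@typeGroups)[unique(object@typeGroups)])),
        collapse = " "), "\n")
})

#' SignatureProfile: per-group z-scored mean expression over a gene set
#'
#' The unit compared by Pearson signature matching: for each gene in an
#' ordered set, group means z-scored across groups (population/n
#' denominator). Genes constant across groups are flagged and excluded from
#' correlations.
#'
#' @slot values genes x groups matrix of z-scores.
#' @slot constant logical per gene; TRUE if the gene was constant across
#'   groups (its row is set to 0).
#' @slot species species tag ("human"/"mouse"/"unknown").
#' @export
setClass("SignatureProfile",
         representation(values = "matrix", constant = "logical",
                        species = "character"))

setValidity("SignatureProfile", function(object) {
    msg <- NULL
    if (length(object@constant) != nrow(object@values))
        msg <- c(msg, "constant flag length must match gene count")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SignatureProfile", function(object) {
    cat("SignatureProfile:", nrow(object@values), "genes x",
        ncol(object@values), "groups (", object@species, ")\n")
    if (any(object@constant))
        cat("  constant genes:",
            paste(rownames(object@values)[object@constant], collapse = ", "),
            "\n")
})
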