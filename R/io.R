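## Plain-text readers and writers for the package's data objects:
## genes x samples TSV tables (first column the gene id), per-sample
## metadata CSV, MTX coordinate triplets plus genes.tsv/barcodes.tsv for
## the single-cell layers, and YAML for generator configurations.

#' Write / read a PanelCohort
#'
#' \code{writePanelCohort} writes \code{counts.tsv} (genes x samples, first
#' column \code{gene}) and \code{metadata.csv};
#' \code{readPanelCohort} reads them back.
#'
#' @param cohort A \linkS4class{PanelCohort}.
#' @param dir output directory (created if needed).
#' @return \code{writePanelCohort}: the directory, invisibly;
#'   \code{readPanelCohort}: a \linkS4class{PanelCohort}.
#' @export
writePanelCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- assay(cohort, "counts")
    utils::write.table(
        data.frame(gene = rownames(cts), cts, check.names = FALSE),
        file.path(dir, "counts.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    md <- as.data.frame(colData(cohort))
    utils::write.csv(data.frame(sample = rownames(md), md,
                                check.names = FALSE),
                     file.path(dir, "metadata.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writePanelCohort
#' @param ref_genes reference gene ids.
#' @export
readPanelCohort <- function(dir, ref_genes = panelReferenceGenes()) {
    cts <- utils::read.delim(file.path(dir, "counts.tsv"),
                             check.names = FALSE)
    mat <- as.matrix(cts[, -1, drop = FALSE])
    rownames(mat) <- cts$gene
    md <- utils::read.csv(file.path(dir, "metadata.csv"))
    stopifnot(identical(md$sample, colnames(mat)))
    flag_cols <- intersect(c("ischemic", "diabetes", "high_bmi", "female"),
                           colnames(md))
    PanelCohort(mat, group = md$group, age = md$age, ref_genes = ref_genes,
                flags = if (length(flag_cols)) md[flag_cols] else NULL,
                true_subcluster = md$true_subcluster)
}

#' Write / read an SCCultureData
#'
#' Writes \code{spliced.mtx}, \code{unspliced.mtx} (MatrixMarket coordinate
#' triplets), \code{genes.tsv}, \code{barcodes.tsv} and \code{cells.csv}
#' (per-cell annotation).
#'
#' @param data An \linkS4class{SCCultureData}.
#' @param dir output directory.
#' @return \code{writeCultureData}: the directory, invisibly;
#'   \code{readCultureData}: an \linkS4class{SCCultureData}.
#' @export
writeCultureData <- function(data, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(spliced(data), sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "spliced.mtx"))
    Matrix::writeMM(methods::as(Matrix::Matrix(unspliced(data),
                                               sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "unspliced.mtx"))
    writeLines(rownames(data), file.path(dir, "genes.tsv"))
    writeLines(colnames(data), file.path(dir, "barcodes.tsv"))
    md <- as.data.frame(colData(data))
    utils::write.csv(data.frame(barcode = rownames(md), md,
                                check.names = FALSE),
                     file.path(dir, "cells.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCultureData
#' @export
readCultureData <- function(dir) {
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    sp <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
    un <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
    dimnames(sp) <- dimnames(un) <- list(genes, cells)
    md <- utils::read.csv(file.path(dir, "cells.csv"))
    out <- SCCultureData(sp, un, batch = factor(md$batch),
                         population = md$population,
                         is_doublet = md$is_doublet,
                         pseudotime = md$pseudotime)
    extra <- setdiff(colnames(md), c("barcode", "batch", "population",
                                     "is_doublet", "pseudotime"))
    for (cn in extra) colData(out)[[cn]] <- md[[cn]]
    out
}

#' Write / read a BulkTimecourse
#'
#' Writes \code{expression.tsv} (genes x samples) and \code{stages.csv}
#' (sample, stage, replicate).
#'
#' @param bulk A \linkS4class{BulkTimecourse}.
#' @param dir output directory.
#' @return \code{writeBulkTimecourse}: the directory, invisibly;
#'   \code{readBulkTimecourse}: a \linkS4class{BulkTimecourse}.
#' @export
writeBulkTimecourse <- function(bulk, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- assay(bulk, "counts")
    utils::write.table(
        data.frame(gene = rownames(cts), cts, check.names = FALSE),
        file.path(dir, "expression.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(
        data.frame(sample = colnames(bulk),
                   stage = as.character(stageLabels(bulk)),
                   replicate = colData(bulk)$replicate),
        file.path(dir, "stages.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writeBulkTimecourse
#' @export
readBulkTimecourse <- function(dir) {
    cts <- utils::read.delim(file.path(dir, "expression.tsv"),
                             check.names = FALSE)
    mat <- as.matrix(cts[, -1, drop = FALSE])
    rownames(mat) <- cts$gene
    md <- utils::read.csv(file.path(dir, "stages.csv"),
                          colClasses = c("character", "character",
                                         "integer"))
    stopifnot(identical(md$sample, colnames(mat)))
    BulkTimecourse(mat, stage = md$stage, replicate = md$replicate)
}

#' Write / read a CellTypeReference
#'
#' Writes \code{reference.tsv} (genes x cell types) and \code{groups.csv}
#' (cell type, pooled group).
#'
#' @param ref A \linkS4class{CellTypeReference}.
#' @param dir output directory.
#' @return \code{writeCellTypeReference}: the directory, invisibly;
#'   \code{readCellTypeReference}: a \linkS4class{CellTypeReference}.
#' @export
writeCellTypeReference <- function(ref, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- categoryMeans(ref)
    utils::write.table(
        data.frame(gene = rownames(m), m, check.names = FALSE),
        file.path(dir, "reference.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(
        data.frame(cell_type = names(typeGroups(ref)),
                   group = unname(typeGroups(ref))),
        file.path(dir, "groups.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCellTypeReference
#' @export
readCellTypeReference <- function(dir) {
    tab <- utils::read.delim(file.path(dir, "reference.tsv"),
                             check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$gene
    gr <- utils::read.csv(file.path(dir, "groups.csv"))
    CellTypeReference(m, stats::setNames(gr$group, gr$cell_type))
}

#' Save / load a generator configuration as YAML
#'
#' @param config a \code{cohortConfig}, \code{cultureConfig} or
#'   \code{timecourseConfig}.
#' @param path YAML file path.
#' @return \code{saveConfig}: the path, invisibly; \code{loadConfig}: the
#'   reconstructed, re-validated config.
#' @export
saveConfig <- function(config, path) {
    x <- unclass(config)
    x$.class <- class(config)[1]
    ## yaml drops names on atomic vectors; store named vectors as maps
    if (!is.null(x$population_fractions))
        x$population_fractions <- as.list(x$population_fractions)
    if (!is.null(x$mixing_weights))
        x$mixing_weights <- list(values = as.vector(x$mixing_weights),
                                 stages = rownames(x$mixing_weights),
                                 populations = colnames(x$mixing_weights))
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
    x <- yaml::read_yaml(path)
    cls <- x$.class
    x$.class <- NULL
    if (!is.null(x$mixing_weights))
        x$mixing_weights <- matrix(
            x$mixing_weights$values,
            nrow = length(x$mixing_weights$stages),
            dimnames = list(x$mixing_weights$stages,
                            x$mixing_weights$populations))
    if (!is.null(x$population_fractions))
        x$population_fractions <- unlist(x$population_fractions)
    if (!is.null(x$flag_probs))
        x$flag_probs <- lapply(x$flag_probs, unlist)
    ctor <- switch(cls,
                   CohortConfig = cohortConfig,
                   CultureConfig = cultureConfig,
                   TimecourseConfig = timecourseConfig,
                   stop("unknown config class: ", cls))
    do.call(ctor, x)
}
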