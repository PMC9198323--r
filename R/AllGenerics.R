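#' Accessors for fibrosig classes
#'
#' \code{spliced}/\code{unspliced} return the two count layers of an
#' \linkS4class{SCCultureData}; \code{refGeneIds} the reference genes of a
#' \linkS4class{PanelCohort}; \code{stageLabels} the ordered stage factor of
#' a \linkS4class{BulkTimecourse}; \code{categoryMeans} and \code{typeGroups}
#' the slots of a \linkS4class{CellTypeReference}; \code{profileValues} the
#' z-score matrix of a \linkS4class{SignatureProfile}.
#'
#' @param x An object of the respective class.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spliced", function(x) standardGeneric("spliced"))
#' @rdname accessors
#' @export
setMethod("spliced", "SCCultureData", function(x) assay(x, "spliced"))

#' @rdname accessors
#' @export
setGeneric("unspliced", function(x) standardGeneric("unspliced"))
#' @rdname accessors
#' @export
setMethod("unspliced", "SCCultureData", function(x) assay(x, "unspliced"))

#' @rdname accessors
#' @export
setGeneric("refGeneIds", function(x) standardGeneric("refGeneIds"))
#' @rdname accessors
#' @export
setMethod("refGeneIds", "PanelCohort", function(x)
    rownames(x)[rowData(x)$is_reference])

#' @rdname accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))
#' @rdname accessors
#' @export
setMethod("stageLabels", "BulkTimecourse", function(x) colData(x)$stage)

#' @rdname accessors
#' @export
setGeneric("categoryMeans", function(x) standardGeneric("categoryMeans"))
#' @rdname accessors
#' @export
setMethod("categoryMeans", "CellTypeReference", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("typeGroups", function(x) standardGeneric("typeGroups"))
#' @rdname accessors
#' @export
setMethod("typeGroups", "CellTypeReference", function(x) x@typeGroups)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "SignatureProfile", function(x) x@values)
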