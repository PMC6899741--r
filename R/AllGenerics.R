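## Accessor generics shared across the package's containers.

#' Accessors for magscore containers
#'
#' Small family of read-only accessors: `magIds()` and `moduleIds()` return
#' the row/column identities of an [MCSMatrix-class]; `sampleIds()` and
#' `entityIds()` the axes of an [AbundanceMatrix-class] or
#' [ZScoreMatrix-class]; `scores()` / `values()` the underlying numeric
#' matrix; `assayType()` the DNA/RNA provenance; `leafOrder()` the dendrogram
#' order of a [ClusterResult-class].
#'
#' @param x a magscore container object.
#' @return character vectors of ids, or a numeric matrix for
#'   `scores()`/`values()`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("magIds", function(x) standardGeneric("magIds"))

#' @rdname accessors
#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("assayType", function(x) standardGeneric("assayType"))

#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @rdname accessors
#' @export
setMethod("magIds", "MCSMatrix", function(x) rownames(x@scores))

#' @rdname accessors
#' @export
setMethod("moduleIds", "MCSMatrix", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setMethod("scores", "MCSMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("entityIds", "AbundanceMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIds", "AbundanceMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("values", "AbundanceMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("assayType", "AbundanceMatrix", function(x) x@assay)

#' @rdname accessors
#' @export
setMethod("assayType", "ReadHitTable", function(x) x@assay)

#' @rdname accessors
#' @export
setMethod("entityIds", "ZScoreMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ZScoreMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("values", "ZScoreMatrix", function(x) x@values)

#' Ids of zero-variance rows of a ZScoreMatrix
#' @param x a [ZScoreMatrix-class]
#' @return character vector of flagged row ids
#' @export
constantRows <- function(x) {
    stopifnot(is(x, "ZScoreMatrix"))
    x@constantRows
}

#' @rdname accessors
#' @export
setMethod("leafOrder", "ClusterResult", function(x) x@leafOrder)

#' Group members of a MagGrouping
#' @param x a [MagGrouping-class]
#' @param group `"A"` or `"B"`
#' @return character vector of MAG ids
#' @export
groupMembers <- function(x, group = c("A", "B")) {
    stopifnot(is(x, "MagGrouping"))
    if (match.arg(group) == "A") x@groupA else x@groupB
}
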