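## Key-gene abundance normalization.
##
## Metagenomes: read hits to a key gene are divided by the average read hits
## to a panel of single-copy marker COGs in the same sample, yielding an
## approximate per-genome copy number. Metatranscriptomes: read hits are
## divided by the sample's total read count (library size). In both assays,
## read hits for ORFs sharing an annotation are averaged first.

#' Mean read hits over ORFs sharing an annotation
#'
#' When multiple ORFs carry the same annotation, their read-hit counts are
#' averaged (ORFs with zero hits are real observations and count toward the
#' mean). An annotation carried by no ORF yields 0.
#'
#' @param table a [ReadHitTable-class].
#' @param annotationId a KO or COG id.
#' @return non-negative mean hit count.
#' @export
meanHitsPerAnnotation <- function(table, annotationId) {
    stopifnot(is(table, "ReadHitTable"), length(annotationId) == 1L)
    h <- table@hits$hits[table@hits$annotation_id == annotationId]
    if (length(h) == 0L) 0 else mean(h)
}

## mean over the KOs of a key gene of the per-KO mean hits; KOs with no
## annotated ORF carry no information and are skipped
geneMeanHits <- function(table, koIds) {
    koIds <- normalizeKoSet(koIds)
    perKo <- vapply(koIds, meanHitsPerAnnotation, numeric(1), table = table)
    seen <- koIds %in% table@hits$annotation_id
    if (!any(seen)) 0 else mean(perKo[seen])
}

#' Validate and normalize a single-copy marker COG panel
#'
#' @param cogIds character vector of COG ids (35 by default, configurable).
#' @param expectedSize panel size to enforce; `NA` disables the check.
#' @return the validated character vector.
#' @export
singleCopyCogSet <- function(cogIds, expectedSize = 35L) {
    cogIds <- as.character(cogIds)
    if (anyDuplicated(cogIds))
        stop("single-copy COG ids must be unique")
    if (!is.na(expectedSize) && length(cogIds) != expectedSize)
        stop(sprintf("expected %d single-copy COGs, got %d",
                     expectedSize, length(cogIds)))
    cogIds
}

#' Single-copy-gene normalized metagenomic gene abundance
#'
#' Divides the (annotation-averaged) metagenomic read hits of a key gene by
#' the average read hits to the single-copy marker COGs, giving an
#' approximate copies-per-genome abundance. Scale-invariant: multiplying
#' every hit count in the sample by a constant leaves the value unchanged.
#'
#' @param table a metagenomic [ReadHitTable-class].
#' @param koIds KO id(s) of the key gene (multi-KO genes average their
#'   per-KO mean hits).
#' @param scg single-copy COG panel, see [singleCopyCogSet()].
#' @return non-negative abundance ratio.
#' @export
normalizeGeneAbundanceMg <- function(table, koIds, scg) {
    stopifnot(is(table, "ReadHitTable"))
    if (table@assay != "metagenome")
        stop("SCG normalization applies to metagenomic tables only")
    denom <- mean(vapply(scg, meanHitsPerAnnotation, numeric(1),
                         table = table))
    if (denom <= 0)
        stop("degenerate denominator: no read hits to any single-copy COG",
             " in sample ", table@sampleId)
    geneMeanHits(table, koIds) / denom
}

#' Library-size normalized transcript abundance
#'
#' Divides the (annotation-averaged) metatranscriptomic read hits of a key
#' gene by the total number of metatranscriptomic reads in the sample.
#' Returns the raw ratio; apply a display scale (e.g. hits per million) at
#' the matrix level, see [buildAbundanceMatrix()].
#'
#' @param table a metatranscriptomic [ReadHitTable-class].
#' @param koIds KO id(s) of the key gene.
#' @return non-negative abundance ratio.
#' @export
normalizeTranscriptAbundance <- function(table, koIds) {
    stopifnot(is(table, "ReadHitTable"))
    if (table@assay != "metatranscriptome")
        stop("library-size normalization applies to metatranscriptomic ",
             "tables only")
    if (table@totalReads <= 0)
        stop("totalReads must be positive for sample ", table@sampleId)
    geneMeanHits(table, koIds) / table@totalReads
}

#' Validate a key-gene catalog
#'
#' @param catalog `data.frame` with columns `category`, `gene_name` and
#'   `ko_ids` (comma-separated KO list).
#' @return the catalog, with genes ordered by category then gene name.
#' @export
keyGeneCatalog <- function(catalog) {
    need <- c("category", "gene_name", "ko_ids")
    if (!is.data.frame(catalog) || !all(need %in% names(catalog)))
        stop("catalog must be a data.frame with columns ",
             paste(need, collapse = ", "))
    if (anyDuplicated(catalog$gene_name))
        stop("gene names must be unique in the key-gene catalog")
    if (any(!nzchar(catalog$category)))
        stop("every catalog entry needs a category")
    catalog[order(catalog$category, catalog$gene_name), , drop = FALSE]
}

catalogKoList <- function(catalog) {
    lapply(strsplit(catalog$ko_ids, ","), function(k) trimws(k))
}

#' Build a normalized key-gene abundance matrix
#'
#' Applies the assay-appropriate normalization per gene and sample:
#' single-copy-COG normalization for metagenomes, library-size
#' normalization (times `displayScale`) for metatranscriptomes. Genes are
#' ordered by catalog category then name; samples keep input order.
#'
#' @param tables list of [ReadHitTable-class], all of one assay.
#' @param catalog key-gene catalog, see [keyGeneCatalog()].
#' @param scg single-copy COG panel (metagenome assay only).
#' @param displayScale display constant applied to metatranscriptome ratios
#'   (default 1e6, i.e. hits per million reads); the value used is recorded
#'   in the result, so raw ratios are always recoverable.
#' @return an [AbundanceMatrix-class] (genes x samples).
#' @export
buildAbundanceMatrix <- function(tables, catalog, scg = NULL,
                                 displayScale = 1e6) {
    stopifnot(length(tables) >= 1L,
              all(vapply(tables, is, logical(1), "ReadHitTable")))
    assays <- unique(vapply(tables, function(t) t@assay, character(1)))
    if (length(assays) != 1L)
        stop("all read-hit tables must share one assay type; got: ",
             paste(assays, collapse = ", "))
    assay <- assays
    catalog <- keyGeneCatalog(catalog)
    koLists <- catalogKoList(catalog)
    sampleIds <- vapply(tables, function(t) t@sampleId, character(1))
    if (assay == "metagenome") {
        if (is.null(scg))
            stop("metagenomic normalization needs a single-copy COG panel")
        vals <- vapply(tables, function(t)
            vapply(koLists, normalizeGeneAbundanceMg, numeric(1),
                   table = t, scg = scg),
            numeric(nrow(catalog)))
        scale <- 1
        norm <- "scg_mean"
    } else {
        vals <- vapply(tables, function(t)
            vapply(koLists, normalizeTranscriptAbundance, numeric(1),
                   table = t),
            numeric(nrow(catalog)))
        vals <- vals * displayScale
        scale <- displayScale
        norm <- "total_reads"
    }
    vals <- matrix(vals, nrow = nrow(catalog),
                   dimnames = list(catalog$gene_name, sampleIds))
    new("AbundanceMatrix", values = vals, assay = assay,
        normalization = norm, displayScale = scale)
}
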