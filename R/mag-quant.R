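## MAG-level quantification: quality/taxonomy filtering, coverage
## normalization, row z-scoring and Ward/Euclidean hierarchical clustering
## of expression profiles.

#' Filter MAGs by genome quality and taxonomy
#'
#' Retains bins with completeness strictly above `minCompleteness` and
#' redundancy strictly below `maxRedundancy` (boundary values are excluded),
#' then removes any MAG whose taxonomy contains one of `excludedOrders`
#' (e.g. seawater-associated lineages mixed in at the point of sampling).
#' Input order is preserved; the operation is idempotent.
#'
#' @param records `data.frame` of MAG metadata with columns `mag_id`,
#'   `completeness`, `redundancy` and any taxonomy rank columns among
#'   `domain`, `phylum`, `class`, `order`.
#' @param minCompleteness completeness threshold in percent (default 70).
#' @param maxRedundancy redundancy threshold in percent (default 10).
#' @param excludedOrders taxonomy labels to drop (default
#'   Pseudomonadales and Sphingomonadales).
#' @return the retained rows of `records`.
#' @examples
#' recs <- data.frame(mag_id = c("a", "b", "c"),
#'                    order = c("Sulfurovum", "Pseudomonadales", "Aquificales"),
#'                    completeness = c(95, 90, 70), redundancy = c(2, 1, 5))
#' filterMags(recs)  # keeps only "a": "b" excluded order, "c" at boundary
#' @export
filterMags <- function(records, minCompleteness = 70, maxRedundancy = 10,
                       excludedOrders = c("Pseudomonadales",
                                          "Sphingomonadales")) {
    need <- c("mag_id", "completeness", "redundancy")
    if (!is.data.frame(records) || !all(need %in% names(records)))
        stop("records must be a data.frame with columns ",
             paste(need, collapse = ", "))
    if (any(records$completeness < 0 | records$completeness > 100,
            na.rm = TRUE) ||
        any(records$redundancy < 0 | records$redundancy > 100, na.rm = TRUE))
        stop("completeness and redundancy must be percentages in [0, 100]")
    keep <- records$completeness > minCompleteness &
        records$redundancy < maxRedundancy
    rankCols <- intersect(c("domain", "phylum", "class", "order"),
                          names(records))
    if (length(excludedOrders) > 0L && length(rankCols) > 0L) {
        tax <- as.matrix(records[rankCols])
        keep <- keep & !apply(tax, 1L, function(r)
            any(r %in% excludedOrders))
    }
    records[keep, , drop = FALSE]
}

#' Normalize per-MAG coverage by sample library size
#'
#' Divides each MAG's mean coverage in a sample by that sample's total read
#' count, making coverages comparable across sequencing depths. Applies to
#' both metagenomic and metatranscriptomic coverage.
#'
#' @param cov a [CoverageMatrix-class].
#' @return an [AbundanceMatrix-class] (MAGs x samples, normalization
#'   `"total_reads"`).
#' @export
normalizeMagCoverage <- function(cov) {
    stopifnot(is(cov, "CoverageMatrix"))
    totals <- cov@sampleTotalReads[colnames(cov@coverage)]
    bad <- names(totals)[!is.finite(totals) | totals <= 0]
    if (length(bad) > 0L)
        stop("non-positive total read count for sample(s): ",
             paste(bad, collapse = ", "))
    vals <- sweep(cov@coverage, 2L, totals, "/")
    new("AbundanceMatrix", values = vals, assay = cov@assay,
        normalization = "total_reads", displayScale = 1)
}

#' Row-wise z-score transformation
#'
#' Centres each row to mean 0 and scales to sample standard deviation 1
#' (n-1 denominator), so a MAG's abundance across samples is expressed
#' relative to its own mean. Zero-variance rows are emitted as all-zero and
#' flagged, keeping the matrix shape stable.
#'
#' @param x an [AbundanceMatrix-class] or a plain numeric matrix with
#'   dimnames, with at least two columns.
#' @return a [ZScoreMatrix-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
#' z <- zscoreRows(m)
#' values(z)          # first row -1, 0, 1; constant row all zero
#' constantRows(z)
#' @export
zscoreRows <- function(x) {
    m <- if (is(x, "AbundanceMatrix")) x@values else x
    stopifnot(is.matrix(m), is.numeric(m))
    if (ncol(m) < 2L)
        stop("z-scoring needs at least 2 columns")
    mu <- rowMeans(m)
    sdev <- apply(m, 1L, stats::sd)
    constant <- sdev == 0
    z <- (m - mu) / ifelse(constant, 1, sdev)
    z[constant, ] <- 0
    new("ZScoreMatrix", values = z,
        constantRows = rownames(m)[constant])
}

#' Hierarchical clustering with Euclidean distance and Ward linkage
#'
#' Agglomerative clustering of matrix rows (or columns) using Euclidean
#' distance and the Ward minimum-variance criterion, as used for
#' expression-profile heatmap dendrograms. Deterministic given its input.
#'
#' @param x a [ZScoreMatrix-class], [AbundanceMatrix-class] or numeric
#'   matrix with dimnames.
#' @param axis cluster `"rows"` (default) or `"columns"`.
#' @return a [ClusterResult-class].
#' @export
clusterRows <- function(x, axis = c("rows", "columns")) {
    axis <- match.arg(axis)
    m <- if (is(x, "ZScoreMatrix") || is(x, "AbundanceMatrix"))
        values(x) else x
    stopifnot(is.matrix(m), is.numeric(m))
    if (axis == "columns") m <- t(m)
    if (nrow(m) < 2L)
        stop("clustering needs at least 2 items on the chosen axis")
    if (is.null(rownames(m)))
        stop("items must be named (matrix dimnames required)")
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
    new("ClusterResult", hc = hc, leafOrder = hc$labels[hc$order],
        method = "ward", metric = "euclidean", axis = axis)
}

#' Cut a clustering into k groups
#'
#' @param cluster a [ClusterResult-class].
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cutClusters <- function(cluster, k) {
    stopifnot(is(cluster, "ClusterResult"))
    stats::cutree(cluster@hc, k = k)
}

#' Reorder a matrix by a clustering's leaf order
#'
#' Applies the dendrogram leaf order obtained on one matrix to another
#' (e.g. ordering the metagenomic heatmap to match the metatranscriptomic
#' clustering). Ids missing from the order keep their position at the end;
#' ids absent from the matrix are ignored.
#'
#' @param x an [AbundanceMatrix-class], [ZScoreMatrix-class] or matrix.
#' @param rowOrder,colOrder a [ClusterResult-class] or character vector of
#'   ids; `NULL` leaves the axis untouched.
#' @return an object of the same class as `x`, reordered.
#' @export
applyClusterOrder <- function(x, rowOrder = NULL, colOrder = NULL) {
    asIds <- function(o) if (is(o, "ClusterResult")) leafOrder(o) else o
    m <- if (isS4(x)) values(x) else x
    if (!is.null(rowOrder)) {
        ids <- asIds(rowOrder)
        m <- m[c(intersect(ids, rownames(m)),
                 setdiff(rownames(m), ids)), , drop = FALSE]
    }
    if (!is.null(colOrder)) {
        ids <- asIds(colOrder)
        m <- m[, c(intersect(ids, colnames(m)),
                   setdiff(colnames(m), ids)), drop = FALSE]
    }
    if (is(x, "AbundanceMatrix"))
        return(new("AbundanceMatrix", values = m, assay = x@assay,
                   normalization = x@normalization,
                   displayScale = x@displayScale))
    if (is(x, "ZScoreMatrix"))
        return(new("ZScoreMatrix", values = m,
                   constantRows = x@constantRows))
    m
}

#' Presence/absence of marker KOs per MAG
#'
#' Reports, for each MAG and each queried KO (e.g. the methanogenesis
#' marker mcrA, K00399), whether any of the MAG's ORFs carries the
#' annotation, with the supporting ORF ids.
#'
#' @param annotations `data.frame` with columns `orf_id`, `mag_id`, `ko_id`.
#' @param koIds KO ids to query.
#' @param magIds optional MAG universe (defaults to MAGs present in the
#'   table; pass explicitly to include MAGs with no annotations).
#' @return `data.frame` with columns `mag_id`, `ko_id`, `present`,
#'   `orf_ids` (comma-separated, empty when absent).
#' @export
koPresenceQuery <- function(annotations, koIds, magIds = NULL) {
    checkAnnotationFrame(annotations)
    koIds <- normalizeKoSet(koIds)
    if (is.null(magIds)) magIds <- unique(annotations$mag_id)
    grid <- expand.grid(ko_id = koIds, mag_id = magIds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[c("mag_id", "ko_id")]
    ann <- annotations
    ann$ko_id <- toupper(ann$ko_id)
    orfs <- mapply(function(mag, ko) {
        hits <- ann$orf_id[ann$mag_id == mag & ann$ko_id == ko]
        paste(sort(unique(hits)), collapse = ",")
    }, grid$mag_id, grid$ko_id)
    grid$present <- nzchar(orfs)
    grid$orf_ids <- unname(orfs)
    rownames(grid) <- NULL
    grid
}
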