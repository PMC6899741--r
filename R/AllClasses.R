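#' @import methods
NULL

KO_PATTERN <- "^K[0-9]{5}$"

## ---- expression tree validation (internal; nodes are plain nested lists) ----

validExpressionNode <- function(node, path = "root") {
    if (!is.list(node) || is.null(node$kind))
        return(sprintf("%s: node is not a tagged list", path))
    switch(node$kind,
        ATOM = {
            if (!is.character(node$ko) || length(node$ko) != 1L ||
                !grepl(KO_PATTERN, node$ko))
                return(sprintf("%s: ATOM must carry one KO id (K#####)", path))
        },
        AND = ,
        OR = {
            if (!is.list(node$children) || length(node$children) < 2L)
                return(sprintf("%s: %s node needs >=2 children",
                               path, node$kind))
            for (i in seq_along(node$children)) {
                msg <- validExpressionNode(node$children[[i]],
                                           sprintf("%s/%s[%d]", path,
                                                   node$kind, i))
                if (!is.null(msg)) return(msg)
            }
        },
        OPTIONAL = {
            if (is.null(node$child))
                return(sprintf("%s: OPTIONAL must wrap one node", path))
            msg <- validExpressionNode(node$child,
                                       sprintf("%s/OPTIONAL", path))
            if (!is.null(msg)) return(msg)
        },
        WILDCARD = NULL,
        return(sprintf("%s: unknown node kind '%s'", path, node$kind))
    )
    NULL
}

## ---- ModuleDefinition ----

#' ModuleDefinition: a parsed metabolic module
#'
#' Holds the boolean expression of one KEGG-style metabolic module as an
#' ordered tree of reaction steps. Top-level space-separated units of the
#' definition are the reaction steps; commas are alternatives (any one
#' sufficient), plus signs are complex components (all required), a minus
#' prefix marks a component optional, and `--` stands for an unspecified
#' enzyme. Build objects with [parseModuleDefinition()].
#'
#' @slot moduleId single module accession, e.g. `"M00567"`.
#' @slot name human-readable module name (may be `""`).
#' @slot root the parsed expression tree (nested tagged lists; internal
#'   representation, inspect via [moduleSteps()] / [serializeDefinition()]).
#' @slot sourceText the original definition string.
#' @seealso [parseModuleDefinition()], [moduleCompletionScore()]
#' @export
setClass("ModuleDefinition",
    representation(moduleId = "character", name = "character",
                   root = "list", sourceText = "character"),
    validity = function(object) {
        if (length(object@moduleId) != 1L || !nzchar(object@moduleId))
            return("moduleId must be a single non-empty string")
        msg <- validExpressionNode(object@root)
        if (!is.null(msg)) return(msg)
        if (length(moduleSteps(object)) < 1L)
            return("module must have at least one top-level step")
        TRUE
    })

#' @describeIn ModuleDefinition compact display
#' @param object a `ModuleDefinition`
#' @export
setMethod("show", "ModuleDefinition", function(object) {
    cat("ModuleDefinition", object@moduleId,
        if (nzchar(object@name)) paste0("(", object@name, ")") else "",
        "\n  steps:", length(moduleSteps(object)),
        " KOs:", length(moduleKos(object)),
        "\n  definition:", object@sourceText, "\n")
})

## ---- ReadHitTable ----

#' ReadHitTable: per-ORF read-hit counts for one sample
#'
#' One sequenced sample's mapped-read counts: one row per (ORF, annotation)
#' with the number of reads hitting that ORF, plus the sample's total read
#' count and assay type. Many reads map nowhere, so hits need not sum to
#' `totalReads`.
#'
#' @slot sampleId sample identifier.
#' @slot hits `data.frame` with columns `orf_id`, `annotation_id` (KO or COG
#'   id) and `hits` (non-negative counts).
#' @slot totalReads total sequenced reads in the sample (positive).
#' @slot assay `"metagenome"` or `"metatranscriptome"`.
#' @export
setClass("ReadHitTable",
    representation(sampleId = "character", hits = "data.frame",
                   totalReads = "numeric", assay = "character"),
    validity = function(object) {
        need <- c("orf_id", "annotation_id", "hits")
        if (!all(need %in% names(object@hits)))
            return(paste("hits must have columns",
                         paste(need, collapse = ", ")))
        if (any(object@hits$hits < 0) || any(!is.finite(object@hits$hits)))
            return("hit counts must be finite and non-negative")
        if (length(object@totalReads) != 1L || object@totalReads <= 0)
            return("totalReads must be a single positive number")
        if (!object@assay %in% c("metagenome", "metatranscriptome"))
            return("assay must be 'metagenome' or 'metatranscriptome'")
        TRUE
    })

#' Construct a ReadHitTable
#'
#' @param sampleId sample identifier.
#' @param hits `data.frame` with columns `orf_id`, `annotation_id`, `hits`.
#' @param totalReads total read count of the sample.
#' @param assay `"metagenome"` or `"metatranscriptome"`.
#' @return a [ReadHitTable-class] object.
#' @examples
#' rht <- ReadHitTable("S1",
#'     data.frame(orf_id = c("o1", "o2"), annotation_id = c("K00399", "K00399"),
#'                hits = c(10, 20)),
#'     totalReads = 1e6, assay = "metagenome")
#' meanHitsPerAnnotation(rht, "K00399")
#' @export
ReadHitTable <- function(sampleId, hits, totalReads, assay) {
    hits$hits <- as.numeric(hits$hits)
    new("ReadHitTable", sampleId = as.character(sampleId), hits = hits,
        totalReads = as.numeric(totalReads), assay = match.arg(
            assay, c("metagenome", "metatranscriptome")))
}

#' @describeIn ReadHitTable compact display
#' @param object a `ReadHitTable`
#' @export
setMethod("show", "ReadHitTable", function(object) {
    cat("ReadHitTable", object@sampleId, sprintf("[%s]", object@assay),
        "\n ", nrow(object@hits), "annotated ORF rows;",
        format(object@totalReads, big.mark = ","), "total reads\n")
})

## ---- MCSMatrix ----

#' MCSMatrix: MAG-by-module completion scores
#'
#' Dense matrix of module completion scores (MCS): rows are MAGs, columns
#' metabolic modules, entries in \[0, 1\]. An MCS of 1 means the MAG encodes a
#' complete pathway, 0 that the pathway is absent; a module absent from a MAG
#' scores 0, never `NA`. Built with [computeMcsMatrix()].
#'
#' @slot scores numeric matrix with MAG rownames and module colnames.
#' @export
setClass("MCSMatrix", representation(scores = "matrix"),
    validity = function(object) {
        s <- object@scores
        if (is.null(rownames(s)) || is.null(colnames(s)))
            return("scores must carry MAG rownames and module colnames")
        if (anyNA(s) || any(s < 0 | s > 1))
            return("all MCS entries must lie in [0, 1] with no missing values")
        TRUE
    })

#' @describeIn MCSMatrix compact display
#' @param object an `MCSMatrix`
#' @export
setMethod("show", "MCSMatrix", function(object) {
    cat("MCSMatrix:", nrow(object@scores), "MAGs x",
        ncol(object@scores), "modules; mean MCS",
        round(mean(object@scores), 3), "\n")
})

## ---- AbundanceMatrix ----

#' AbundanceMatrix: normalized entity-by-sample abundances
#'
#' Non-negative normalized abundances of entities (key genes or MAGs) across
#' samples, tagged with assay provenance and the normalization applied:
#' `"scg_mean"` (metagenomic read hits divided by the mean read hits to
#' single-copy marker genes) or `"total_reads"` (hits or coverage divided by
#' sample library size).
#'
#' @slot values numeric matrix, entities as rows, samples as columns.
#' @slot assay `"metagenome"` or `"metatranscriptome"`.
#' @slot normalization `"scg_mean"` or `"total_reads"`.
#' @slot displayScale multiplicative display constant already applied to
#'   `values` (1 = raw ratios); divide by it to recover raw ratios.
#' @export
setClass("AbundanceMatrix",
    representation(values = "matrix", assay = "character",
                   normalization = "character", displayScale = "numeric"),
    prototype(displayScale = 1),
    validity = function(object) {
        v <- object@values
        if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
            return("values must be finite and non-negative")
        if (is.null(rownames(v)) || is.null(colnames(v)))
            return("values must carry entity rownames and sample colnames")
        if (!object@assay %in% c("metagenome", "metatranscriptome"))
            return("assay must be 'metagenome' or 'metatranscriptome'")
        if (!object@normalization %in% c("scg_mean", "total_reads", "none"))
            return("unknown normalization tag")
        if (length(object@displayScale) != 1L || object@displayScale <= 0)
            return("displayScale must be a single positive number")
        TRUE
    })

#' @describeIn AbundanceMatrix compact display
#' @param object an `AbundanceMatrix`
#' @export
setMethod("show", "AbundanceMatrix", function(object) {
    cat("AbundanceMatrix [", object@assay, ", ", object@normalization,
        "]: ", nrow(object@values), " entities x ", ncol(object@values),
        " samples", if (object@displayScale != 1)
            paste0(" (displayScale ", object@displayScale, ")"), "\n",
        sep = "")
})

## ---- CoverageMatrix ----

#' CoverageMatrix: per-MAG mean coverage across samples
#'
#' Average per-base read coverage of each MAG in each sample of one assay,
#' together with the per-sample total read counts used for normalization.
#'
#' @slot coverage non-negative numeric matrix, MAGs x samples.
#' @slot sampleTotalReads named positive totals, one per sample column.
#' @slot assay `"metagenome"` or `"metatranscriptome"`.
#' @export
setClass("CoverageMatrix",
    representation(coverage = "matrix", sampleTotalReads = "numeric",
                   assay = "character"),
    validity = function(object) {
        cv <- object@coverage
        if (is.null(rownames(cv)) || is.null(colnames(cv)))
            return("coverage must carry MAG rownames and sample colnames")
        if (anyNA(cv) || any(cv < 0))
            return("coverage must be non-negative with no missing values")
        if (!identical(sort(names(object@sampleTotalReads)),
                       sort(colnames(cv))))
            return("sampleTotalReads must be named by the sample columns")
        if (!object@assay %in% c("metagenome", "metatranscriptome"))
            return("assay must be 'metagenome' or 'metatranscriptome'")
        TRUE
    })

#' Construct a CoverageMatrix
#'
#' @param coverage MAGs-by-samples mean coverage matrix (dimnames required).
#' @param sampleTotalReads totals named by sample id.
#' @param assay `"metagenome"` or `"metatranscriptome"`.
#' @return a [CoverageMatrix-class].
#' @export
CoverageMatrix <- function(coverage, sampleTotalReads, assay) {
    new("CoverageMatrix", coverage = coverage,
        sampleTotalReads = sampleTotalReads[colnames(coverage)],
        assay = match.arg(assay, c("metagenome", "metatranscriptome")))
}

#' @describeIn CoverageMatrix compact display
#' @param object a `CoverageMatrix`
#' @export
setMethod("show", "CoverageMatrix", function(object) {
    cat("CoverageMatrix [", object@assay, "]: ", nrow(object@coverage),
        " MAGs x ", ncol(object@coverage), " samples\n", sep = "")
})

## ---- ZScoreMatrix ----

#' ZScoreMatrix: row-wise z-scored abundances
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation 1
#' (n-1 denominator); rows with zero variance are emitted as all-zero and
#' flagged in `constantRows` so the matrix shape stays stable for plotting.
#'
#' @slot values numeric matrix of z-scores.
#' @slot constantRows ids of rows that had zero variance.
#' @export
setClass("ZScoreMatrix",
    representation(values = "matrix", constantRows = "character"),
    validity = function(object) {
        if (anyNA(object@values) || any(!is.finite(object@values)))
            return("z-scores must be finite")
        if (!all(object@constantRows %in% rownames(object@values)))
            return("constantRows must name rows of the matrix")
        TRUE
    })

#' @describeIn ZScoreMatrix compact display
#' @param object a `ZScoreMatrix`
#' @export
setMethod("show", "ZScoreMatrix", function(object) {
    cat("ZScoreMatrix:", nrow(object@values), "rows x",
        ncol(object@values), "columns;",
        length(object@constantRows), "constant row(s) flagged\n")
})

## ---- ClusterResult ----

#' ClusterResult: a Ward/Euclidean hierarchical clustering
#'
#' Wraps the merge tree produced by agglomerative clustering with Euclidean
#' distance and Ward linkage, plus the dendrogram leaf order. Convert to
#' Newick with [writeNewick()] and cut into k groups with [cutClusters()].
#'
#' @slot hc the `stats::hclust` merge tree.
#' @slot leafOrder item ids in dendrogram order.
#' @slot method linkage criterion (always `"ward"`).
#' @slot metric distance metric (always `"euclidean"`).
#' @slot axis `"rows"` or `"columns"` of the clustered matrix.
#' @export
setClass("ClusterResult",
    representation(hc = "ANY", leafOrder = "character",
                   method = "character", metric = "character",
                   axis = "character"),
    validity = function(object) {
        if (!inherits(object@hc, "hclust"))
            return("hc must be an hclust object")
        if (!setequal(object@leafOrder, object@hc$labels) ||
            anyDuplicated(object@leafOrder))
            return("leafOrder must be a permutation of the item ids")
        TRUE
    })

#' @describeIn ClusterResult compact display
#' @param object a `ClusterResult`
#' @export
setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult (", object@metric, "/", object@method, ") over ",
        length(object@leafOrder), " ", object@axis, "\n", sep = "")
})

## ---- MagGrouping ----

#' MagGrouping: a two-group partition of MAGs
#'
#' Disjoint, non-empty sets of MAG ids used for per-module enrichment tests,
#' e.g. MAGs expressed at one vent field versus everywhere else. Built from
#' transcript profiles with [assignExpressionGroups()] or read from a file
#' with [readGrouping()].
#'
#' @slot groupA,groupB disjoint non-empty character vectors of MAG ids.
#' @slot label human-readable description of the split.
#' @slot excluded MAG ids dropped before grouping (e.g. all-zero transcript
#'   rows).
#' @export
setClass("MagGrouping",
    representation(groupA = "character", groupB = "character",
                   label = "character", excluded = "character"),
    prototype(excluded = character(0), label = ""),
    validity = function(object) {
        if (length(object@groupA) == 0L || length(object@groupB) == 0L)
            return("both groups must be non-empty")
        if (length(intersect(object@groupA, object@groupB)) > 0L)
            return("groups must be disjoint")
        TRUE
    })

#' @describeIn MagGrouping compact display
#' @param object a `MagGrouping`
#' @export
setMethod("show", "MagGrouping", function(object) {
    cat("MagGrouping", if (nzchar(object@label))
            sprintf("'%s'", object@label), ":",
        length(object@groupA), "vs", length(object@groupB), "MAGs",
        if (length(object@excluded))
            sprintf("(%d excluded)", length(object@excluded)), "\n")
})

## ---- SimulationConfig ----

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Fixes the scale and structure of a simulated vent-fluid study: number of
#' MAGs, metagenome and metatranscriptome samples, metabolic modules,
#' planted expression blocks, noise level and group-wise module-completion
#' shift. Defaults reproduce the scale of the real study design the package
#' models: 64 retained MAGs (73 bins of which 9 fall in seawater-associated
#' excluded orders), 15 metagenomes, 10 metatranscriptomes, 56 modules.
#'
#' @slot nMags MAGs passing quality/taxonomy filters (default 64).
#' @slot nExcludedOrder extra high-quality bins in excluded orders
#'   (default 9, giving 73 bins total).
#' @slot nQualityFail extra bins failing completeness/redundancy thresholds
#'   (default 0).
#' @slot nMgSamples metagenome samples (default 15).
#' @slot nMtSamples metatranscriptome samples (default 10).
#' @slot nModules metabolic modules (default 56).
#' @slot nGroups planted sample/expression blocks (default 5).
#' @slot seed integer seed fixing every downstream draw.
#' @slot noiseCv lognormal coefficient of variation of coverage noise
#'   (default 0.25).
#' @slot blockSeparation fold-difference between in-block and out-of-block
#'   mean coverage (default 10).
#' @slot decoupledFraction fraction of MAGs whose metagenomic block differs
#'   from their metatranscriptomic block (default 0.1).
#' @slot plantedShift mean MCS difference planted between MAG groups for
#'   enriched modules (default 0.6).
#' @slot nEnriched number of modules carrying the planted shift (default 6).
#' @slot taxonomyLabels order-level labels cycled over MAGs.
#' @export
setClass("SimulationConfig",
    representation(nMags = "integer", nExcludedOrder = "integer",
                   nQualityFail = "integer", nMgSamples = "integer",
                   nMtSamples = "integer", nModules = "integer",
                   nGroups = "integer", seed = "integer",
                   noiseCv = "numeric", blockSeparation = "numeric",
                   decoupledFraction = "numeric", plantedShift = "numeric",
                   nEnriched = "integer", taxonomyLabels = "character"),
    validity = function(object) {
        counts <- c(object@nMags, object@nMgSamples, object@nMtSamples,
                    object@nModules, object@nGroups)
        if (any(counts < 1L)) return("all counts must be positive")
        if (object@noiseCv < 0) return("noiseCv must be >= 0")
        if (object@nGroups > object@nMtSamples)
            return("nGroups cannot exceed nMtSamples")
        if (object@decoupledFraction < 0 || object@decoupledFraction > 1)
            return("decoupledFraction must lie in [0, 1]")
        if (object@plantedShift < 0 || object@plantedShift > 1)
            return("plantedShift must lie in [0, 1]")
        TRUE
    })

#' Construct a SimulationConfig
#'
#' @param nMags,nExcludedOrder,nQualityFail,nMgSamples,nMtSamples,nModules,nGroups,seed,noiseCv,blockSeparation,decoupledFraction,plantedShift,nEnriched,taxonomyLabels
#'   see [SimulationConfig-class] for meanings and defaults.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 7, nMags = 12, nModules = 8,
#'                         nMtSamples = 4, nMgSamples = 6, nGroups = 2)
#' cfg
#' @export
simulationConfig <- function(nMags = 64L, nExcludedOrder = 9L,
                             nQualityFail = 0L, nMgSamples = 15L,
                             nMtSamples = 10L, nModules = 56L,
                             nGroups = 5L, seed = 1L, noiseCv = 0.25,
                             blockSeparation = 10, decoupledFraction = 0.1,
                             plantedShift = 0.6, nEnriched = 6L,
                             taxonomyLabels = c(
                                 "Sulfurovum", "Aquificales", "Thiotrichales",
                                 "Methanococci", "Methanomicrobia",
                                 "Desulfobacterales", "Archaeoglobi",
                                 "Nanoarchaea")) {
    new("SimulationConfig", nMags = as.integer(nMags),
        nExcludedOrder = as.integer(nExcludedOrder),
        nQualityFail = as.integer(nQualityFail),
        nMgSamples = as.integer(nMgSamples),
        nMtSamples = as.integer(nMtSamples),
        nModules = as.integer(nModules), nGroups = as.integer(nGroups),
        seed = as.integer(seed), noiseCv = noiseCv,
        blockSeparation = blockSeparation,
        decoupledFraction = decoupledFraction, plantedShift = plantedShift,
        nEnriched = as.integer(nEnriched), taxonomyLabels = taxonomyLabels)
}

#' @describeIn SimulationConfig compact display
#' @param object a `SimulationConfig`
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: ", object@nMags, " MAGs (+",
        object@nExcludedOrder, " excluded-order, +", object@nQualityFail,
        " low-quality), ", object@nMgSamples, " MG / ", object@nMtSamples,
        " MT samples, ", object@nModules, " modules, ", object@nGroups,
        " blocks, seed ", object@seed, "\n", sep = "")
})
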