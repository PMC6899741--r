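## Module completion scoring.
##
## The module completion score (MCS) of a MAG for a module is the mean, over
## the module's reaction steps, of the proportion of required orthologs the
## MAG possesses for that step. Alternatives (OR) take the best alternative
## (any one combination suffices to complete the step); components of a
## combination (AND) contribute proportional credit (the mean of their
## completeness). Optional components never change a score; the unspecified
## enzyme wildcard counts as present.

normalizeKoSet <- function(kos) {
    if (length(kos) == 0L) return(character(0))
    unique(toupper(as.character(kos)))
}

## Returns a score in [0,1], or NA when the node is vacuous (optional, or a
## group consisting only of optional parts) and must be excluded from its
## parent's mean.
scoreNode <- function(node, kos) {
    switch(node$kind,
        ATOM = if (node$ko %in% kos) 1 else 0,
        WILDCARD = 1,
        OPTIONAL = NA_real_,
        AND = {
            v <- vapply(node$children, scoreNode, numeric(1), kos = kos)
            v <- v[!is.na(v)]
            if (length(v) == 0L) NA_real_ else mean(v)
        },
        OR = {
            v <- vapply(node$children, scoreNode, numeric(1), kos = kos)
            v <- v[!is.na(v)]
            if (length(v) == 0L) NA_real_ else max(v)
        },
        stop("unknown node kind: ", node$kind)
    )
}

#' Completeness of one expression node against a KO set
#'
#' Recursive scoring contract: an atom scores 1 if its KO is in the set and
#' 0 otherwise; an all-required group (serial steps or an enzyme complex)
#' scores the mean of its parts; a group of alternatives scores the best
#' alternative; the `--` wildcard scores 1. Optional components are excluded
#' from their parent's mean; querying an optional node directly returns its
#' wrapped component's score.
#'
#' @param node an expression node (e.g. an element of [moduleSteps()]).
#' @param kos character vector of KO ids possessed (case-insensitive;
#'   duplicates collapse).
#' @return a score in \[0, 1\].
#' @export
nodeCompleteness <- function(node, kos) {
    kos <- normalizeKoSet(kos)
    while (identical(node$kind, "OPTIONAL")) node <- node$child
    v <- scoreNode(node, kos)
    if (is.na(v)) {
        ## group made only of optional parts: score it with the optional
        ## wrappers treated as transparent rather than fail
        transparent <- function(n) {
            switch(n$kind,
                ATOM = if (n$ko %in% kos) 1 else 0,
                WILDCARD = 1,
                OPTIONAL = transparent(n$child),
                AND = mean(vapply(n$children, transparent, numeric(1))),
                OR = max(vapply(n$children, transparent, numeric(1))))
        }
        v <- transparent(node)
    }
    v
}

#' Module completion score of a KO set
#'
#' The MCS is a real number between 0 and 1: the completeness proportions of
#' all reaction steps in the module are averaged into a single score. A MAG
#' carrying every ortholog of the module scores exactly 1 (complete
#' pathway); a MAG carrying none of them scores exactly 0 for a
#' wildcard-free module (pathway absent).
#'
#' @param module a [ModuleDefinition-class].
#' @param kos character vector of KO ids possessed by the MAG.
#' @return MCS in \[0, 1\].
#' @examples
#' m <- parseModuleDefinition("M1", "K00001 (K00002,K00003)")
#' moduleCompletionScore(m, "K00001")           # step1 complete, step2 absent
#' moduleCompletionScore(m, c("K00001", "K00003"))
#' @export
moduleCompletionScore <- function(module, kos) {
    stopifnot(is(module, "ModuleDefinition"))
    kos <- normalizeKoSet(kos)
    v <- vapply(moduleSteps(module), scoreNode, numeric(1), kos = kos)
    v <- v[!is.na(v)]
    if (length(v) == 0L) 0 else mean(v)
}

#' KO sets per MAG from an annotation table
#'
#' Collapses an ORF-level KO annotation table to one KO set per MAG (the
#' union of KO annotations over all ORFs binned into the MAG; duplicate
#' annotations collapse, ids are upper-cased).
#'
#' @param annotations `data.frame` with columns `orf_id`, `mag_id`, `ko_id`.
#' @return named list of character vectors, one per MAG (in first-appearance
#'   order).
#' @export
magKoSets <- function(annotations) {
    checkAnnotationFrame(annotations)
    mags <- unique(annotations$mag_id)
    sets <- lapply(split(toupper(annotations$ko_id), annotations$mag_id),
                   unique)
    sets[mags]
}

checkAnnotationFrame <- function(annotations) {
    need <- c("orf_id", "mag_id", "ko_id")
    if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
        stop("annotations must be a data.frame with columns ",
             paste(need, collapse = ", "))
    invisible(annotations)
}

#' Compute the MAG-by-module MCS matrix
#'
#' For each MAG the KO set is the union of KO annotations over all its ORFs;
#' each matrix entry is the module completion score of that set against one
#' module. Every entry is filled: a module absent from a MAG scores 0,
#' never `NA`.
#'
#' @param annotations `data.frame` with columns `orf_id`, `mag_id`, `ko_id`
#'   (one KO per row; unannotated ORFs may be omitted).
#' @param modules list of [ModuleDefinition-class] objects.
#' @param magIds optional character vector fixing the MAG universe and row
#'   order; annotation rows referencing MAGs outside it are an error, and
#'   MAGs with no annotations get all-zero rows.
#' @return an [MCSMatrix-class].
#' @export
computeMcsMatrix <- function(annotations, modules, magIds = NULL) {
    checkAnnotationFrame(annotations)
    if (length(modules) == 0L) stop("module list must be non-empty")
    stopifnot(all(vapply(modules, is, logical(1), "ModuleDefinition")))
    sets <- magKoSets(annotations)
    if (is.null(magIds)) {
        magIds <- names(sets)
    } else {
        unknown <- setdiff(names(sets), magIds)
        if (length(unknown) > 0L)
            stop("annotation rows reference unknown MAG ids: ",
                 paste(unknown, collapse = ", "))
    }
    modIds <- vapply(modules, function(m) m@moduleId, character(1))
    scores <- matrix(0, nrow = length(magIds), ncol = length(modules),
                     dimnames = list(magIds, modIds))
    for (i in seq_along(magIds)) {
        kos <- sets[[magIds[i]]]
        if (is.null(kos)) kos <- character(0)
        scores[i, ] <- vapply(modules, moduleCompletionScore, numeric(1),
                              kos = kos)
    }
    new("MCSMatrix", scores = scores)
}
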