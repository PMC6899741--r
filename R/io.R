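## TSV / flat-file / Newick / JSON interchange.
##
## Tolerant reader, strict writer: readers validate required headers,
## accept (and warn about) unknown extra columns, and report offending line
## numbers; writers emit a fixed canonical layout so reruns are
## byte-identical.

readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "", comment.char = "")
}

checkColumns <- function(df, required, path, keepExtra = FALSE) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
        stop("missing column(s) ", paste(missing, collapse = ", "),
             " in ", path)
    extra <- setdiff(names(df), required)
    if (length(extra) > 0L && !keepExtra)
        warning("ignoring unknown column(s) ",
                paste(extra, collapse = ", "), " in ", path)
    if (keepExtra) df else df[required]
}

## data line numbers (header is line 1)
badLines <- function(idx) paste(idx + 1L, collapse = ", ")

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}

writeMatrixTsv <- function(m, path, idColumn = "id", digits = NA) {
    vals <- if (is.na(digits)) m else {
        matrix(formatC(m, digits = digits, format = "f"),
               nrow = nrow(m), dimnames = dimnames(m))
    }
    df <- data.frame(rownames(m), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(idColumn, colnames(m))
    writeTsv(df, path)
}

readMatrixTsv <- function(path, idColumn = NULL) {
    df <- readTsv(path)
    if (is.null(idColumn)) idColumn <- names(df)[1]
    if (!idColumn %in% names(df))
        stop("missing id column '", idColumn, "' in ", path)
    ids <- df[[idColumn]]
    rest <- df[setdiff(names(df), idColumn)]
    m <- as.matrix(rest)
    mode(m) <- "numeric"
    if (anyNA(m)) {
        bad <- which(apply(is.na(m), 1L, any))
        stop("non-numeric matrix value(s) in ", path, " at line(s) ",
             badLines(bad))
    }
    rownames(m) <- ids
    m
}

#' Read an ORF-level KO annotation table
#'
#' @param path TSV with header columns `orf_id`, `mag_id`, `ko_id` (one KO
#'   per row; ORFs without KO annotations may be omitted). Unknown extra
#'   columns are accepted with a warning.
#' @return `data.frame` with the three columns, KO ids upper-cased.
#' @export
readAnnotations <- function(path) {
    df <- checkColumns(readTsv(path), c("orf_id", "mag_id", "ko_id"), path)
    df$ko_id <- toupper(df$ko_id)
    bad <- which(!grepl(KO_PATTERN, df$ko_id))
    if (length(bad) > 0L)
        stop("malformed KO id(s) in ", path, " at line(s) ",
             badLines(bad))
    df
}

#' Read module definitions (TSV or KEGG-flat-file style)
#'
#' Two formats are supported and auto-detected: a two/three-column TSV
#' (`module_id`, `definition`, optional `name`), or KEGG-flat-file-style
#' records with `ENTRY`, `NAME` and `DEFINITION` lines (continuation lines
#' indented, records separated by `///`).
#'
#' @param path input file.
#' @param format `"auto"` (default), `"tsv"` or `"kegg"`.
#' @return list of [ModuleDefinition-class].
#' @export
readModuleDefinitions <- function(path, format = c("auto", "tsv", "kegg")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        first <- readLines(path, n = 1L, warn = FALSE)
        format <- if (grepl("^ENTRY\\b", first)) "kegg" else "tsv"
    }
    if (format == "tsv") {
        df <- readTsv(path)
        df <- checkColumns(df, c("module_id", "definition"), path,
                           keepExtra = TRUE)
        nm <- if ("name" %in% names(df)) df$name else rep("", nrow(df))
        return(lapply(seq_len(nrow(df)), function(i)
            tryCatch(parseModuleDefinition(df$module_id[i],
                                           df$definition[i], nm[i]),
                     magscore_parse_error = function(e)
                         stop("module ", df$module_id[i], " (line ",
                              i + 1L, " of ", path, "): ",
                              conditionMessage(e), call. = FALSE))))
    }
    ## KEGG flat-file records
    lines <- readLines(path, warn = FALSE)
    mods <- list()
    entry <- name <- ""
    def <- character(0)
    inDef <- FALSE
    flush <- function() {
        if (nzchar(entry)) {
            mods[[length(mods) + 1L]] <<- parseModuleDefinition(
                entry, paste(trimws(def), collapse = " "), name)
        }
        entry <<- ""; name <<- ""; def <<- character(0); inDef <<- FALSE
    }
    for (ln in lines) {
        if (grepl("^///", ln)) { flush(); next }
        key <- sub("^([A-Z_]*)\\s.*$", "\\1", ln)
        if (identical(key, "ENTRY")) {
            entry <- strsplit(trimws(sub("^ENTRY", "", ln)),
                              "\\s+")[[1]][1]
            inDef <- FALSE
        } else if (identical(key, "NAME")) {
            name <- trimws(sub("^NAME", "", ln))
            inDef <- FALSE
        } else if (identical(key, "DEFINITION")) {
            def <- c(def, trimws(sub("^DEFINITION", "", ln)))
            inDef <- TRUE
        } else if (grepl("^\\s", ln) && inDef) {
            def <- c(def, trimws(ln))       # continuation line
        } else {
            inDef <- FALSE
        }
    }
    flush()
    mods
}

#' Write module definitions as TSV
#'
#' @param modules list of [ModuleDefinition-class].
#' @param path output TSV (`module_id`, `name`, `definition`; the original
#'   source text is preserved).
#' @return the path, invisibly.
#' @export
writeModuleDefinitions <- function(modules, path) {
    writeTsv(data.frame(
        module_id = vapply(modules, function(m) m@moduleId, character(1)),
        name = vapply(modules, function(m) m@name, character(1)),
        definition = vapply(modules, function(m) m@sourceText,
                            character(1))), path)
}

#' Read the sample table
#'
#' @param path TSV with columns `sample_id`, `assay`
#'   (`metagenome`/`metatranscriptome`) and `total_reads`; optional `site`
#'   and `field` columns are kept for expression grouping.
#' @return `data.frame`.
#' @export
readSampleTable <- function(path) {
    df <- readTsv(path)
    need <- c("sample_id", "assay", "total_reads")
    keep <- c(need, intersect(c("site", "field"), names(df)))
    if (!all(need %in% names(df)))
        stop("missing column(s) ", paste(setdiff(need, names(df)),
                                         collapse = ", "), " in ", path)
    df <- df[keep]
    df$total_reads <- suppressWarnings(as.numeric(df$total_reads))
    bad <- which(is.na(df$total_reads) | df$total_reads <= 0)
    if (length(bad) > 0L)
        stop("invalid total_reads in ", path, " at line(s) ",
             badLines(bad))
    if (!all(df$assay %in% c("metagenome", "metatranscriptome")))
        stop("assay must be 'metagenome' or 'metatranscriptome' in ", path)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in ", path)
    df
}

#' Read a MAG-by-sample coverage matrix
#'
#' @param path TSV: first column `mag_id`, one numeric column per sample.
#' @param sampleTable sample table (see [readSampleTable()]) providing the
#'   totals and assay for the matrix's samples.
#' @param assay which assay's samples to expect.
#' @return a [CoverageMatrix-class].
#' @export
readCoverageMatrix <- function(path, sampleTable, assay) {
    assay <- match.arg(assay, c("metagenome", "metatranscriptome"))
    m <- readMatrixTsv(path, "mag_id")
    st <- sampleTable[sampleTable$assay == assay, , drop = FALSE]
    missing <- setdiff(colnames(m), st$sample_id)
    if (length(missing) > 0L)
        stop("sample(s) ", paste(missing, collapse = ", "), " in ", path,
             " missing from the sample table")
    totals <- st$total_reads
    names(totals) <- st$sample_id
    CoverageMatrix(m, totals, assay)
}

#' Read MAG metadata
#'
#' @param path TSV with columns `mag_id`, `completeness`, `redundancy` and
#'   optionally `domain`, `phylum`, `class`, `order`, `length_bp`.
#' @return `data.frame`.
#' @export
readMagMetadata <- function(path) {
    df <- readTsv(path)
    need <- c("mag_id", "completeness", "redundancy")
    keep <- c("mag_id", intersect(c("domain", "phylum", "class", "order"),
                                  names(df)),
              "completeness", "redundancy",
              intersect("length_bp", names(df)))
    if (!all(need %in% names(df)))
        stop("missing column(s) ", paste(setdiff(need, names(df)),
                                         collapse = ", "), " in ", path)
    df <- df[keep]
    for (col in c("completeness", "redundancy")) {
        df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(df[[col]]))
        if (length(bad) > 0L)
            stop("non-numeric ", col, " in ", path, " at line(s) ",
                 badLines(bad))
    }
    if (anyDuplicated(df$mag_id)) stop("duplicate MAG ids in ", path)
    df
}

#' Read the key-gene catalog
#'
#' @param path TSV with columns `category`, `gene_name`, `ko_ids`
#'   (comma-separated KO list).
#' @return validated catalog `data.frame` (see [keyGeneCatalog()]).
#' @export
readKeyGeneCatalog <- function(path) {
    keyGeneCatalog(checkColumns(readTsv(path),
                                c("category", "gene_name", "ko_ids"),
                                path))
}

#' Read the single-copy COG panel
#'
#' @param path TSV with a `cog_id` column.
#' @param expectedSize panel size to enforce (default 35; `NA` disables).
#' @return character vector of COG ids.
#' @export
readScgSet <- function(path, expectedSize = 35L) {
    df <- checkColumns(readTsv(path), "cog_id", path)
    singleCopyCogSet(df$cog_id, expectedSize)
}

#' Read per-sample read-hit tables
#'
#' @param path TSV with columns `sample_id`, `orf_id`, `annotation_id`,
#'   `hits`.
#' @param sampleTable sample table providing totals and assay per sample.
#' @return named list of [ReadHitTable-class], in sample-table order.
#' @export
readReadHitTables <- function(path, sampleTable) {
    df <- checkColumns(readTsv(path),
                       c("sample_id", "orf_id", "annotation_id", "hits"),
                       path)
    df$hits <- suppressWarnings(as.numeric(df$hits))
    bad <- which(is.na(df$hits) | df$hits < 0)
    if (length(bad) > 0L)
        stop("invalid hit count(s) in ", path, " at line(s) ",
             badLines(bad))
    missing <- setdiff(unique(df$sample_id), sampleTable$sample_id)
    if (length(missing) > 0L)
        stop("sample(s) ", paste(missing, collapse = ", "), " in ", path,
             " missing from the sample table")
    ids <- intersect(sampleTable$sample_id, unique(df$sample_id))
    out <- lapply(ids, function(s) {
        row <- sampleTable[sampleTable$sample_id == s, ]
        ReadHitTable(s, df[df$sample_id == s,
                           c("orf_id", "annotation_id", "hits")],
                     totalReads = row$total_reads, assay = row$assay)
    })
    names(out) <- ids
    out
}

#' Read an explicit MAG grouping
#'
#' @param path TSV with columns `mag_id` and `group` (values `A` or `B`).
#' @param label grouping label to attach.
#' @return a [MagGrouping-class].
#' @export
readGrouping <- function(path, label = basename(path)) {
    df <- checkColumns(readTsv(path), c("mag_id", "group"), path)
    bad <- which(!df$group %in% c("A", "B"))
    if (length(bad) > 0L)
        stop("group must be 'A' or 'B' in ", path, " at line(s) ",
             badLines(bad))
    new("MagGrouping", groupA = df$mag_id[df$group == "A"],
        groupB = df$mag_id[df$group == "B"], label = label)
}

#' Write / read an MCS matrix as TSV
#'
#' MAGs as rows, modules as columns, 4-decimal fixed-point values.
#'
#' @param mcs an [MCSMatrix-class].
#' @param path output / input TSV.
#' @return `writeMcsMatrix`: the path, invisibly; `readMcsMatrix`: an
#'   [MCSMatrix-class].
#' @export
writeMcsMatrix <- function(mcs, path) {
    stopifnot(is(mcs, "MCSMatrix"))
    writeMatrixTsv(scores(mcs), path, idColumn = "mag_id", digits = 4)
}

#' @rdname writeMcsMatrix
#' @export
readMcsMatrix <- function(path) {
    new("MCSMatrix", scores = readMatrixTsv(path, "mag_id"))
}

#' Write an abundance or z-score matrix as TSV
#'
#' @param x an [AbundanceMatrix-class], [ZScoreMatrix-class] or matrix.
#' @param path output TSV.
#' @param idColumn name of the row-id column (default `"id"`).
#' @return the path, invisibly.
#' @export
writeAbundanceMatrix <- function(x, path, idColumn = "id") {
    m <- if (isS4(x)) values(x) else x
    writeMatrixTsv(m, path, idColumn = idColumn)
}

#' Write enrichment results as TSV
#'
#' @param results `data.frame` from [enrichModules()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeEnrichmentResults <- function(results, path) {
    writeTsv(results, path)
}

#' Serialize a clustering as a Newick tree
#'
#' Leaf names are the clustered ids; branch lengths are merge-height
#' deltas. The tree can be re-read with any standard Newick reader.
#'
#' @param cluster a [ClusterResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(cluster, path) {
    stopifnot(is(cluster, "ClusterResult"))
    ape::write.tree(ape::as.phylo(cluster@hc), file = path)
    invisible(path)
}
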