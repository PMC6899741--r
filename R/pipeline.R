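## End-to-end orchestration: quality filter -> key-gene abundances ->
## MAG coverage profiles (normalize, z-score, cluster) -> MCS matrix ->
## per-module enrichment, with a self-describing run manifest.

withStage <- function(stage, code) {
    tryCatch(code, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full functional-profiling pipeline
#'
#' Consumes an input directory laid out as written by [simulateDataset()]
#' (`modules.tsv`, `annotations.tsv`, `mag_metadata.tsv`,
#' `coverage_metagenome.tsv`, `coverage_metatranscriptome.tsv`,
#' `samples.tsv`, and optionally `key_genes.tsv` + `scg.tsv` +
#' `readhits_*.tsv` and `grouping.tsv`) and writes all derived results to
#' `outDir`: the MCS matrix, normalized and z-scored MAG abundance
#' matrices (the metagenomic matrix additionally reordered to the
#' metatranscriptomic clustering), MAG/sample dendrograms as Newick plus
#' flat leaf orders, key-gene abundance matrices when read hits are
#' provided, the per-module enrichment table, and a machine-readable
#' `manifest.json` (configuration, input checksums, versions). The run is
#' deterministic: identical inputs and settings give byte-identical
#' outputs.
#'
#' @param inputDir directory of input TSVs.
#' @param outDir output directory (created; files are overwritten).
#' @param focal focal expression label for the enrichment grouping;
#'   default: the first `field` value in the sample table. Ignored when
#'   `grouping.tsv` is present.
#' @param partition group MAGs by expression `"field"` or `"site"`.
#' @param minCompleteness,maxRedundancy,excludedOrders MAG filter settings,
#'   see [filterMags()].
#' @param alpha,correction enrichment test settings, see [enrichModules()].
#' @param displayScale display constant for transcript gene abundances,
#'   see [buildAbundanceMatrix()].
#' @param seed recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @return invisibly, a list with the main result objects and `outDir`.
#' @export
runPipeline <- function(inputDir, outDir, focal = NULL,
                        partition = c("field", "site"),
                        minCompleteness = 70, maxRedundancy = 10,
                        excludedOrders = c("Pseudomonadales",
                                           "Sphingomonadales"),
                        alpha = 0.05,
                        correction = c("none", "benjamini_hochberg"),
                        displayScale = 1e6, seed = 1L) {
    partition <- match.arg(partition)
    correction <- match.arg(correction)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(inputDir, f)

    meta <- withStage("read_metadata", readMagMetadata(p("mag_metadata.tsv")))
    samples <- withStage("read_samples", readSampleTable(p("samples.tsv")))
    retained <- withStage("filter_mags",
        filterMags(meta, minCompleteness, maxRedundancy, excludedOrders))
    if (nrow(retained) == 0L)
        stop("stage 'filter_mags' failed: no MAG passes the filters")
    magIds <- retained$mag_id
    writeTsv(retained, file.path(outDir, "mags_retained.tsv"))

    ## MAG coverage profiles
    profiles <- withStage("mag_profiles", {
        covMg <- readCoverageMatrix(p("coverage_metagenome.tsv"), samples,
                                    "metagenome")
        covMt <- readCoverageMatrix(p("coverage_metatranscriptome.tsv"),
                                    samples, "metatranscriptome")
        keep <- function(cov) CoverageMatrix(
            cov@coverage[intersect(rownames(cov@coverage), magIds), ,
                         drop = FALSE],
            cov@sampleTotalReads, cov@assay)
        abMg <- normalizeMagCoverage(keep(covMg))
        abMt <- normalizeMagCoverage(keep(covMt))
        zMg <- zscoreRows(abMg)
        zMt <- zscoreRows(abMt)
        ## MAG and sample dendrograms follow the transcript profiles; the
        ## metagenomic heatmap is reordered to match them
        magClust <- clusterRows(zMt, "rows")
        sampleClust <- clusterRows(zMt, "columns")
        list(abMg = abMg, abMt = abMt, zMg = zMg, zMt = zMt,
             magClust = magClust, sampleClust = sampleClust)
    })
    withStage("write_profiles", {
        writeAbundanceMatrix(profiles$abMg,
            file.path(outDir, "mag_abundance_metagenome.tsv"), "mag_id")
        writeAbundanceMatrix(profiles$abMt,
            file.path(outDir, "mag_abundance_metatranscriptome.tsv"),
            "mag_id")
        writeAbundanceMatrix(applyClusterOrder(profiles$zMt,
                                               profiles$magClust,
                                               profiles$sampleClust),
            file.path(outDir, "mag_zscore_metatranscriptome.tsv"),
            "mag_id")
        writeAbundanceMatrix(applyClusterOrder(profiles$zMg,
                                               profiles$magClust),
            file.path(outDir, "mag_zscore_metagenome.tsv"), "mag_id")
        writeNewick(profiles$magClust,
                    file.path(outDir, "cluster_mags.newick"))
        writeNewick(profiles$sampleClust,
                    file.path(outDir, "cluster_samples.newick"))
        writeLines(leafOrder(profiles$magClust),
                   file.path(outDir, "mag_leaf_order.txt"))
        writeLines(leafOrder(profiles$sampleClust),
                   file.path(outDir, "sample_leaf_order.txt"))
    })

    ## MCS matrix
    annotations <- withStage("read_annotations",
                             readAnnotations(p("annotations.tsv")))
    mcs <- withStage("mcs_matrix", {
        modules <- readModuleDefinitions(p("modules.tsv"))
        ann <- annotations[annotations$mag_id %in% magIds, , drop = FALSE]
        computeMcsMatrix(ann, modules, magIds = magIds)
    })
    writeMcsMatrix(mcs, file.path(outDir, "mcs_matrix.tsv"))

    ## key-gene abundances (optional inputs)
    geneFiles <- c("key_genes.tsv", "scg.tsv", "readhits_metagenome.tsv",
                   "readhits_metatranscriptome.tsv")
    if (all(file.exists(p(geneFiles)))) {
        withStage("gene_abundance", {
            catalog <- readKeyGeneCatalog(p("key_genes.tsv"))
            scg <- readScgSet(p("scg.tsv"))
            mgTabs <- readReadHitTables(p("readhits_metagenome.tsv"),
                                        samples)
            mtTabs <- readReadHitTables(
                p("readhits_metatranscriptome.tsv"), samples)
            writeAbundanceMatrix(
                buildAbundanceMatrix(mgTabs, catalog, scg),
                file.path(outDir, "gene_abundance_metagenome.tsv"),
                "gene_name")
            writeAbundanceMatrix(
                buildAbundanceMatrix(mtTabs, catalog,
                                     displayScale = displayScale),
                file.path(outDir, "gene_abundance_metatranscriptome.tsv"),
                "gene_name")
        })
    }

    ## enrichment
    enrichment <- withStage("enrichment", {
        grouping <- if (file.exists(p("grouping.tsv"))) {
            readGrouping(p("grouping.tsv"))
        } else {
            if (is.null(focal)) {
                if (!"field" %in% names(samples))
                    stop("no grouping.tsv and no field column in the ",
                         "sample table")
                focal <- samples$field[samples$assay ==
                                       "metatranscriptome"][1]
            }
            assignExpressionGroups(profiles$abMt, samples, partition,
                                   focal)
        }
        enrichModules(mcs, grouping, alpha = alpha,
                      correction = correction)
    })
    writeEnrichmentResults(enrichment,
                           file.path(outDir, "enrichment.tsv"))

    ## manifest (no timestamps: reruns must be byte-identical)
    withStage("manifest", {
        inputs <- list.files(inputDir, full.names = TRUE)
        manifest <- list(
            package = "magscore",
            version = as.character(utils::packageVersion("magscore")),
            r_version = R.version.string,
            seed = seed,
            settings = list(focal = focal, partition = partition,
                            min_completeness = minCompleteness,
                            max_redundancy = maxRedundancy,
                            excluded_orders = excludedOrders,
                            alpha = alpha, correction = correction,
                            display_scale = displayScale,
                            clustering = list(metric = "euclidean",
                                              linkage = "ward")),
            inputs = as.list(stats::setNames(
                unname(tools::md5sum(inputs)), basename(inputs))),
            outputs = sort(setdiff(list.files(outDir), "manifest.json")))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    invisible(list(outDir = outDir, retained = retained, mcs = mcs,
                   profiles = profiles, enrichment = enrichment))
}
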