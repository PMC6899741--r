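## Seeded synthetic-study generator.
##
## Emulates the shape of a genome-resolved vent-fluid study: KO-annotated
## ORFs binned into MAGs, KEGG-style module definitions, per-MAG coverage
## across metagenome and metatranscriptome samples with site-restricted
## block structure, MAG quality metadata, and key-gene read-hit tables —
## all with planted, recorded ground truth and full determinism under one
## seed.

## run code under a temporary RNG state so generators never disturb the
## caller's random stream
withSeed <- function(seed, code) {
    hadSeed <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

## named substream per generator stage, all derived from the one config seed
stageSeed <- function(config, stage) {
    offset <- c(modules = 11L, annotations = 23L, coverage = 37L,
                metadata = 53L, readhits = 71L)[[stage]]
    (config@seed * 131L + offset) %% 2147483587L
}

magIdsFor <- function(config) sprintf("MAG%03d", seq_len(config@nMags))

## block membership shared by the annotation and coverage generators so the
## planted MCS shifts line up with the planted expression blocks
magMtBlocks <- function(config) {
    b <- rep_len(seq_len(config@nGroups), config@nMags)
    names(b) <- magIdsFor(config)
    b
}

## ---- module definitions ----

#' Generate a grammar-covering corpus of module definitions
#'
#' Emits `nModules` synthetic metabolic module definitions spanning every
#' operator of the definition grammar: plain step chains, alternatives,
#' enzyme complexes, nested parenthesized groups, optional components and
#' the unspecified-enzyme wildcard. Each module uses 2-12 synthetic KO ids
#' drawn from the reserved K9xxxx range (disjoint across modules, so
#' planted per-module KO sets never interfere). Fully deterministic under
#' the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list of [ModuleDefinition-class].
#' @export
generateModuleDefinitions <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(stageSeed(config, "modules"), {
        counter <- 0L
        nextKos <- function(n) {
            ids <- sprintf("K9%04d", counter + seq_len(n))
            counter <<- counter + n
            if (counter > 9999L) stop("synthetic KO id range exhausted")
            ids
        }
        templates <- c("chain", "complex", "alternatives",
                       "complex_alternatives", "nested", "optional",
                       "wildcard", "wide")
        lapply(seq_len(config@nModules), function(i) {
            tmpl <- if (i <= length(templates)) templates[i]
                    else sample(templates, 1L)
            def <- switch(tmpl,
                chain = {
                    k <- nextKos(sample(2:6, 1L))
                    paste(k, collapse = " ")
                },
                complex = {
                    k <- nextKos(sample(3:5, 1L))
                    nc <- sample(2:(length(k) - 1L), 1L)
                    paste(c(paste(k[seq_len(nc)], collapse = "+"),
                            k[-seq_len(nc)]), collapse = " ")
                },
                alternatives = {
                    k <- nextKos(sample(3:6, 1L))
                    paste(c(sprintf("(%s,%s)", k[1], k[2]),
                            k[-(1:2)]), collapse = " ")
                },
                complex_alternatives = {
                    k <- nextKos(5L)
                    sprintf("(%s+%s,%s+%s) %s",
                            k[1], k[2], k[3], k[4], k[5])
                },
                nested = {
                    k <- nextKos(sample(4:6, 1L))
                    paste(c(sprintf("((%s,%s) %s)", k[1], k[2], k[3]),
                            k[-(1:3)]), collapse = " ")
                },
                optional = {
                    k <- nextKos(sample(3:5, 1L))
                    paste(c(sprintf("%s-%s", k[1], k[2]),
                            k[-(1:2)]), collapse = " ")
                },
                wildcard = {
                    k <- nextKos(sample(2:4, 1L))
                    paste(c(k[1], "--", k[-1]), collapse = " ")
                },
                wide = {
                    ## larger modules, up to the 12-KO corpus ceiling
                    k <- nextKos(sample(9:12, 1L))
                    rest <- k[-(1:6)]
                    paste(c(sprintf("(%s,%s,%s)", k[1], k[2], k[3]),
                            sprintf("(%s+%s,%s)", k[4], k[5], k[6]),
                            rest), collapse = " ")
                })
            parseModuleDefinition(sprintf("M9%04d", i), def,
                                  name = sprintf("synthetic pathway %d", i))
        })
    })
}

## ---- planted-MCS annotations ----

## achievable step scores with a minimal witness KO subset each; optional
## components carry no weight and are ignored during enumeration
stepAchievable <- function(step) {
    strip <- function(node) {      # essential KOs only
        switch(node$kind,
            ATOM = node$ko,
            WILDCARD = character(0),
            OPTIONAL = character(0),
            unique(unlist(lapply(node$children, strip))))
    }
    kos <- unique(unlist(strip(step)))
    if (length(kos) == 0L)  # wildcard-only or all-optional step
        return(list(scores = nodeCompleteness(step, character(0)),
                    witnesses = list(character(0))))
    stopifnot(length(kos) <= 16L)
    best <- new.env(parent = emptyenv())
    for (mask in 0:(2^length(kos) - 1L)) {
        subset <- kos[bitwAnd(mask, 2^(seq_along(kos) - 1L)) > 0L]
        sc <- scoreNode(step, subset)
        if (is.na(sc)) sc <- nodeCompleteness(step, subset)
        key <- sprintf("%.10f", sc)
        cur <- best[[key]]
        if (is.null(cur) || length(subset) < length(cur))
            best[[key]] <- subset
    }
    keys <- ls(best)
    scoresV <- as.numeric(keys)
    ord <- order(scoresV)
    list(scores = scoresV[ord],
         witnesses = lapply(keys[ord], function(k) best[[k]]))
}

## greedy per-step fill: walk the steps tracking the remaining target mass
## and pick the closest achievable step score each time
plantModuleKos <- function(achievable, target) {
    nSteps <- length(achievable)
    remaining <- target * nSteps
    kos <- character(0)
    chosen <- numeric(nSteps)
    for (s in seq_len(nSteps)) {
        desired <- remaining / (nSteps - s + 1L)
        sc <- achievable[[s]]$scores
        pick <- which.min(abs(sc - desired))
        chosen[s] <- sc[pick]
        kos <- c(kos, achievable[[s]]$witnesses[[pick]])
        remaining <- remaining - chosen[s]
    }
    list(kos = kos, realized = mean(chosen))
}

#' Generate KO annotations with planted module completion
#'
#' For every MAG-module pair a target completion score is drawn (uniform
#' over \{0, 0.25, 0.5, 0.75, 1\}); KO subsets realizing the nearest
#' achievable score are placed constructively (greedy per-step fill
#' honouring best-alternative semantics) and distributed over synthetic ORF
#' ids. A subset of modules carries a planted group-wise completion shift:
#' MAGs of expression block 1 receive high targets and all others low
#' targets, `plantedShift` apart, for the enrichment power analyses.
#' Infeasible targets are snapped to the nearest achievable value; the
#' ground truth records what was actually planted.
#'
#' @param config a [SimulationConfig-class].
#' @param modules list of [ModuleDefinition-class], typically from
#'   [generateModuleDefinitions()].
#' @return list with `annotations` (`data.frame` of `orf_id`, `mag_id`,
#'   `ko_id`) and `truth` (list: `plantedMcs` snapped target matrix,
#'   `requestedMcs` pre-snap targets, `enrichedModules`,
#'   `magBlocks`, `plantedShift`).
#' @export
generateAnnotations <- function(config, modules) {
    stopifnot(is(config, "SimulationConfig"), length(modules) >= 1L)
    withSeed(stageSeed(config, "annotations"), {
        mags <- magIdsFor(config)
        blocks <- magMtBlocks(config)
        modIds <- vapply(modules, function(m) m@moduleId, character(1))
        nEnriched <- min(config@nEnriched, length(modules))
        enriched <- modIds[seq_len(nEnriched)]
        grid <- c(0, 0.25, 0.5, 0.75, 1)
        requested <- matrix(sample(grid, length(mags) * length(modIds),
                                   replace = TRUE),
                            nrow = length(mags),
                            dimnames = list(mags, modIds))
        for (mod in enriched) {
            hi <- sample(c(0.8, 1.0), length(mags), replace = TRUE)
            requested[, mod] <- ifelse(blocks == 1L, hi,
                                       pmax(0, hi - config@plantedShift))
        }
        achievableByModule <- lapply(modules, function(m)
            lapply(moduleSteps(m), stepAchievable))
        planted <- requested
        rows <- vector("list", length(mags))
        for (i in seq_along(mags)) {
            magKos <- character(0)
            for (j in seq_along(modules)) {
                res <- plantModuleKos(achievableByModule[[j]],
                                      requested[i, j])
                planted[i, j] <- res$realized
                magKos <- c(magKos, res$kos)
            }
            if (length(magKos) == 0L) next
            ## one ORF per KO; every 7th KO gets a duplicate ORF so that
            ## same-annotation collapsing is exercised
            orf <- sprintf("%s_orf%04d", mags[i], seq_along(magKos))
            dup <- seq_along(magKos) %% 7L == 0L
            rows[[i]] <- data.frame(
                orf_id = c(orf, sprintf("%s_orfdup%04d", mags[i],
                                        which(dup))),
                mag_id = mags[i],
                ko_id = c(magKos, magKos[dup]))
        }
        annotations <- do.call(rbind, rows[!vapply(rows, is.null,
                                                   logical(1))])
        rownames(annotations) <- NULL
        list(annotations = annotations,
             truth = list(plantedMcs = planted, requestedMcs = requested,
                          enrichedModules = enriched, magBlocks = blocks,
                          plantedShift = config@plantedShift))
    })
}

## ---- coverage ----

#' Generate block-structured MAG coverage for both assays
#'
#' Implements a planted block model of site-restricted expression: each MAG
#' belongs to one sample block where its mean coverage is high
#' (`blockSeparation`-fold above the outside-block mean), with
#' multiplicative lognormal noise of coefficient of variation `noiseCv`
#' (mean 1, so `noiseCv = 0` reproduces the block means exactly). A
#' `decoupledFraction` of MAGs get a metagenomic block differing from their
#' metatranscriptomic block, emulating populations whose DNA and RNA
#' abundance patterns disagree. Per-sample total read counts are drawn
#' uniformly (metagenomes 2e7-6e7, metatranscriptomes 1e7-4e7).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `mg` and `mt` ([CoverageMatrix-class]), `samples`
#'   (`data.frame`: `sample_id`, `assay`, `total_reads`, `site`, `field`)
#'   and `truth` (block memberships and decoupled MAG ids).
#' @export
generateCoverage <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(stageSeed(config, "coverage"), {
        mags <- magIdsFor(config)
        mtBlock <- magMtBlocks(config)
        nDec <- ceiling(config@decoupledFraction * config@nMags)
        decoupled <- if (nDec > 0L && config@nGroups > 1L)
            sort(sample(mags, nDec)) else character(0)
        mgBlock <- mtBlock
        mgBlock[decoupled] <- (mtBlock[decoupled] %% config@nGroups) + 1L
        mkAssay <- function(prefix, nSamples, magBlock, lo, hi) {
            sampleIds <- sprintf("%s%02d", prefix, seq_len(nSamples))
            sampleBlock <- rep_len(seq_len(config@nGroups), nSamples)
            names(sampleBlock) <- sampleIds
            baseMean <- 50
            mu <- outer(magBlock, sampleBlock, function(mb, sb)
                ifelse(mb == sb, baseMean,
                       baseMean / config@blockSeparation))
            dimnames(mu) <- list(mags, sampleIds)
            covm <- if (config@noiseCv > 0) {
                sdlog <- sqrt(log(1 + config@noiseCv^2))
                mu * matrix(stats::rlnorm(length(mu),
                                          meanlog = -sdlog^2 / 2,
                                          sdlog = sdlog),
                            nrow = nrow(mu))
            } else mu
            totals <- round(stats::runif(nSamples, lo, hi))
            names(totals) <- sampleIds
            list(cov = covm, totals = totals, sampleBlock = sampleBlock)
        }
        mg <- mkAssay("MG", config@nMgSamples, mgBlock, 2e7, 6e7)
        mt <- mkAssay("MT", config@nMtSamples, mtBlock, 1e7, 4e7)
        siteOf <- function(b) sprintf("site%d", b)
        fieldOf <- function(b) ifelse(b <= max(1L, config@nGroups %/% 2L),
                                      "Piccard", "VonDamm")
        samples <- rbind(
            data.frame(sample_id = colnames(mg$cov), assay = "metagenome",
                       total_reads = unname(mg$totals),
                       site = siteOf(mg$sampleBlock),
                       field = fieldOf(mg$sampleBlock)),
            data.frame(sample_id = colnames(mt$cov),
                       assay = "metatranscriptome",
                       total_reads = unname(mt$totals),
                       site = siteOf(mt$sampleBlock),
                       field = fieldOf(mt$sampleBlock)))
        list(mg = CoverageMatrix(mg$cov, mg$totals, "metagenome"),
             mt = CoverageMatrix(mt$cov, mt$totals, "metatranscriptome"),
             samples = samples,
             truth = list(mtBlock = mtBlock, mgBlock = mgBlock,
                          mtSampleBlock = mt$sampleBlock,
                          mgSampleBlock = mg$sampleBlock,
                          decoupled = decoupled))
    })
}

## ---- MAG metadata ----

#' Generate MAG quality/taxonomy metadata
#'
#' Emits `nMags` records passing the quality and taxonomy filters
#' (completeness drawn in (70, 100], redundancy in \[0, 10)), plus
#' `nExcludedOrder` high-quality bins in the excluded seawater-associated
#' orders (Pseudomonadales/Sphingomonadales) and `nQualityFail` bins
#' failing the completeness or redundancy threshold.
#'
#' @param config a [SimulationConfig-class].
#' @return `data.frame` with columns `mag_id`, `domain`, `phylum`, `class`,
#'   `order`, `completeness`, `redundancy`, `length_bp`.
#' @export
generateMagMetadata <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(stageSeed(config, "metadata"), {
        archaeal <- c("Methanococci", "Methanomicrobia", "Archaeoglobi",
                      "Nanoarchaea", "Nanohaloarchaea", "Thermoprotei")
        mags <- magIdsFor(config)
        ord <- rep_len(config@taxonomyLabels, config@nMags)
        passing <- data.frame(
            mag_id = mags,
            domain = ifelse(ord %in% archaeal, "Archaea", "Bacteria"),
            phylum = sprintf("phylum_of_%s", ord),
            class = sprintf("class_of_%s", ord),
            order = ord,
            completeness = stats::runif(config@nMags, 70.5, 100),
            redundancy = stats::runif(config@nMags, 0, 9.5),
            length_bp = round(stats::runif(config@nMags, 6e5, 5e6)))
        extra <- list(passing)
        if (config@nExcludedOrder > 0L) {
            n <- config@nExcludedOrder
            seaOrd <- rep_len(c("Pseudomonadales", "Sphingomonadales"), n)
            extra <- c(extra, list(data.frame(
                mag_id = sprintf("SEA%02d", seq_len(n)),
                domain = "Bacteria", phylum = "Proteobacteria",
                class = "Gammaproteobacteria", order = seaOrd,
                completeness = stats::runif(n, 70.5, 100),
                redundancy = stats::runif(n, 0, 9.5),
                length_bp = round(stats::runif(n, 2e6, 6e6)))))
        }
        if (config@nQualityFail > 0L) {
            n <- config@nQualityFail
            lowComp <- seq_len(n) %% 2L == 1L
            extra <- c(extra, list(data.frame(
                mag_id = sprintf("LOWQ%02d", seq_len(n)),
                domain = "Bacteria", phylum = "unclassified",
                class = "unclassified",
                order = rep_len(config@taxonomyLabels, n),
                completeness = ifelse(lowComp,
                                      stats::runif(n, 30, 70),
                                      stats::runif(n, 70.5, 100)),
                redundancy = ifelse(lowComp, stats::runif(n, 0, 9.5),
                                    stats::runif(n, 10, 30)),
                length_bp = round(stats::runif(n, 5e5, 4e6)))))
        }
        out <- do.call(rbind, extra)
        rownames(out) <- NULL
        out
    })
}

## ---- key-gene read hits ----

#' The synthetic key-gene catalog
#'
#' A fixed catalog of key metabolic genes by category (sulphur, nitrogen,
#' methane, hydrogen, carbon), each mapping to one or more KO ids. The
#' methanogenesis marker mcrA carries its real KO (K00399); all other KOs
#' are synthetic (reserved K8xxxx range).
#'
#' @return `data.frame` with columns `category`, `gene_name`, `ko_ids`.
#' @export
generateKeyGeneCatalog <- function() {
    keyGeneCatalog(data.frame(
        category = c("sulphur", "sulphur", "sulphur",
                     "nitrogen", "nitrogen", "nitrogen", "nitrogen",
                     "methane", "methane",
                     "hydrogen", "hydrogen",
                     "carbon", "carbon"),
        gene_name = c("soxB", "dsrA", "aprA",
                      "napA", "narB", "nirA", "nifH",
                      "mcrA", "pmoA",
                      "hyaB", "hybC",
                      "rbcL", "aclB"),
        ko_ids = c("K80001", "K80002", "K80003",
                   "K80010", "K80011", "K80012", "K80013",
                   "K00399", "K80020",
                   "K80030,K80031", "K80032",
                   "K80040", "K80041")))
}

#' The synthetic single-copy COG panel
#'
#' @param n panel size (default 35, the conventional normalization panel).
#' @return character vector of synthetic COG ids.
#' @export
generateScgSet <- function(n = 35L) {
    singleCopyCogSet(sprintf("COG9%03d", seq_len(n)), expectedSize = n)
}

#' Generate key-gene read-hit tables with planted abundances
#'
#' Constructs per-sample read-hit tables whose normalized abundances equal
#' planted values exactly: every single-copy COG receives the same hit
#' count per metagenome sample (so the normalization denominator is exact),
#' and gene hit counts are planted multiples of it; metatranscriptome gene
#' hits are planted counts against the sample's total reads.
#'
#' @param config a [SimulationConfig-class].
#' @param catalog key-gene catalog (default [generateKeyGeneCatalog()]).
#' @param scg single-copy COG panel (default [generateScgSet()]).
#' @return list with `mg`, `mt` (lists of [ReadHitTable-class]) and `truth`
#'   (`mgAbundance`, `mtAbundance`: planted normalized gene-by-sample
#'   matrices; metatranscriptomic values in hits per million reads).
#' @export
generateReadHits <- function(config, catalog = generateKeyGeneCatalog(),
                             scg = generateScgSet()) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(stageSeed(config, "readhits"), {
        catalog <- keyGeneCatalog(catalog)
        koLists <- catalogKoList(catalog)
        genes <- catalog$gene_name
        scgHits <- 200
        mgIds <- sprintf("MG%02d", seq_len(config@nMgSamples))
        mtIds <- sprintf("MT%02d", seq_len(config@nMtSamples))
        ## planted copies-per-genome values on a 0.05 grid
        mgTruth <- matrix(sample(seq(0, 3, by = 0.05),
                                 length(genes) * length(mgIds),
                                 replace = TRUE),
                          nrow = length(genes),
                          dimnames = list(genes, mgIds))
        mg <- lapply(mgIds, function(s) {
            geneRows <- do.call(rbind, lapply(seq_along(genes), function(g)
                data.frame(orf_id = sprintf("%s_%s_orf%d", s, genes[g],
                                            seq_along(koLists[[g]])),
                           annotation_id = koLists[[g]],
                           hits = mgTruth[g, s] * scgHits)))
            scgRows <- data.frame(orf_id = sprintf("%s_scg%02d", s,
                                                   seq_along(scg)),
                                  annotation_id = scg, hits = scgHits)
            ReadHitTable(s, rbind(geneRows, scgRows),
                         totalReads = 4e7, assay = "metagenome")
        })
        ## planted transcript counts; truth recorded as hits per million
        mtTotal <- 2e7
        mtCounts <- matrix(sample(seq(0, 4000, by = 20),
                                  length(genes) * length(mtIds),
                                  replace = TRUE),
                           nrow = length(genes),
                           dimnames = list(genes, mtIds))
        mt <- lapply(mtIds, function(s) {
            rows <- do.call(rbind, lapply(seq_along(genes), function(g)
                data.frame(orf_id = sprintf("%s_%s_orf%d", s, genes[g],
                                            seq_along(koLists[[g]])),
                           annotation_id = koLists[[g]],
                           hits = mtCounts[g, s])))
            ReadHitTable(s, rows, totalReads = mtTotal,
                         assay = "metatranscriptome")
        })
        list(mg = mg, mt = mt,
             truth = list(mgAbundance = mgTruth,
                          mtAbundance = mtCounts / mtTotal * 1e6))
    })
}

## ---- full bundle ----

#' Write a complete synthetic study bundle to disk
#'
#' Generates every fixture the pipeline consumes — module definitions, KO
#' annotations, MAG metadata, per-assay coverage matrices, a sample table,
#' the key-gene catalog, the single-copy COG panel and per-sample read-hit
#' tables — and writes them as TSV files plus a `ground_truth.json`
#' recording everything that was planted. Identical configs (including the
#' seed) produce byte-identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the generated objects and `dir`.
#' @export
simulateDataset <- function(config, dir) {
    stopifnot(is(config, "SimulationConfig"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    modules <- generateModuleDefinitions(config)
    ann <- generateAnnotations(config, modules)
    cov <- generateCoverage(config)
    meta <- generateMagMetadata(config)
    catalog <- generateKeyGeneCatalog()
    scg <- generateScgSet()
    hits <- generateReadHits(config, catalog, scg)

    writeModuleDefinitions(modules, file.path(dir, "modules.tsv"))
    writeTsv(ann$annotations, file.path(dir, "annotations.tsv"))
    writeTsv(meta, file.path(dir, "mag_metadata.tsv"))
    writeMatrixTsv(cov$mg@coverage, file.path(dir,
                   "coverage_metagenome.tsv"), idColumn = "mag_id")
    writeMatrixTsv(cov$mt@coverage, file.path(dir,
                   "coverage_metatranscriptome.tsv"), idColumn = "mag_id")
    writeTsv(cov$samples, file.path(dir, "samples.tsv"))
    writeTsv(catalog, file.path(dir, "key_genes.tsv"))
    writeTsv(data.frame(cog_id = scg), file.path(dir, "scg.tsv"))
    writeReadHits <- function(tables, path) {
        rows <- do.call(rbind, lapply(tables, function(t)
            cbind(sample_id = t@sampleId, t@hits)))
        writeTsv(rows, path)
    }
    writeReadHits(hits$mg, file.path(dir, "readhits_metagenome.tsv"))
    writeReadHits(hits$mt, file.path(dir, "readhits_metatranscriptome.tsv"))
    asLabelled <- function(m) list(row_ids = rownames(m),
                                   col_ids = colnames(m), values = m)
    truth <- list(
        config = configAsList(config),
        plantedMcs = asLabelled(ann$truth$plantedMcs),
        requestedMcs = asLabelled(ann$truth$requestedMcs),
        enrichedModules = ann$truth$enrichedModules,
        magBlocks = as.list(ann$truth$magBlocks),
        plantedShift = ann$truth$plantedShift,
        coverage = list(mtBlock = as.list(cov$truth$mtBlock),
                        mgBlock = as.list(cov$truth$mgBlock),
                        mtSampleBlock = as.list(cov$truth$mtSampleBlock),
                        mgSampleBlock = as.list(cov$truth$mgSampleBlock),
                        decoupled = cov$truth$decoupled),
        geneAbundance = list(mg = asLabelled(hits$truth$mgAbundance),
                             mt = asLabelled(hits$truth$mtAbundance)))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(dir = dir, config = config, modules = modules,
                   annotations = ann, coverage = cov, metadata = meta,
                   catalog = catalog, scg = scg, readHits = hits))
}

configAsList <- function(config) {
    slots <- slotNames(config)
    out <- lapply(slots, function(s) slot(config, s))
    names(out) <- slots
    out
}
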