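test_that("the generator is fully deterministic under one seed", {
    cfg <- simulationConfig(seed = 61, nMags = 10, nModules = 10,
                            nMtSamples = 4, nMgSamples = 5, nGroups = 2,
                            nExcludedOrder = 2, nQualityFail = 1)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateDataset(cfg, d1)
    simulateDataset(cfg, d2)
    files <- list.files(d1)
    expect_true(length(files) >= 10)
    for (f in files)
        expect_identical(readLines(file.path(d1, f), warn = FALSE),
                         readLines(file.path(d2, f), warn = FALSE),
                         label = f)
    # a different seed changes the data
    d3 <- withr::local_tempdir()
    simulateDataset(simulationConfig(seed = 62, nMags = 10, nModules = 10,
                                     nMtSamples = 4, nMgSamples = 5,
                                     nGroups = 2, nExcludedOrder = 2,
                                     nQualityFail = 1), d3)
    expect_false(identical(
        readLines(file.path(d1, "annotations.tsv"), warn = FALSE),
        readLines(file.path(d3, "annotations.tsv"), warn = FALSE)))
})

test_that("the definition corpus covers every operator class and parses", {
    mods <- generateModuleDefinitions(simulationConfig(seed = 67))
    defs <- vapply(mods, function(m) m@sourceText, character(1))
    expect_length(mods, 56L)
    expect_true(any(grepl(",", defs)))          # alternatives
    expect_true(any(grepl("\\+", defs)))        # complexes
    expect_true(any(grepl("\\(", defs)))        # grouping
    expect_true(any(grepl("--", defs)))         # wildcard
    expect_true(any(grepl("[K0-9]-K", defs)))   # optional component
    expect_true(any(!grepl("[,+()-]", defs)))   # plain chains
    nkos <- vapply(mods, function(m) length(moduleKos(m)), integer(1))
    expect_true(all(nkos >= 2 & nkos <= 12))
    # disjoint KO pools across modules
    expect_false(anyDuplicated(unlist(lapply(mods, moduleKos))) > 0)
})

test_that("planted MCS targets are realized on the annotation table", {
    cfg <- simulationConfig(seed = 71, nMags = 12, nModules = 16,
                            nGroups = 3, nMtSamples = 6)
    mods <- generateModuleDefinitions(cfg)
    ann <- generateAnnotations(cfg, mods)
    mcs <- computeMcsMatrix(ann$annotations, mods,
                            magIds = rownames(ann$truth$plantedMcs))
    recovered <- scores(mcs)[rownames(ann$truth$plantedMcs),
                             colnames(ann$truth$plantedMcs)]
    # constructive placement: recovered equals the snapped planted truth
    expect_lt(max(abs(recovered - ann$truth$plantedMcs)), 1e-12)
    # and stays within the snapping tolerance of the requested grid
    expect_lt(max(abs(recovered - ann$truth$requestedMcs)), 0.5)
    expect_true(all(ann$truth$enrichedModules %in%
                    vapply(mods, function(m) m@moduleId, character(1))))
})

test_that("planted group-wise MCS shifts separate the expression blocks", {
    cfg <- simulationConfig(seed = 73, nMags = 20, nModules = 10,
                            nGroups = 2, nMtSamples = 6)
    mods <- generateModuleDefinitions(cfg)
    ann <- generateAnnotations(cfg, mods)
    blocks <- ann$truth$magBlocks
    for (mod in ann$truth$enrichedModules) {
        hi <- mean(ann$truth$plantedMcs[blocks == 1L, mod])
        lo <- mean(ann$truth$plantedMcs[blocks != 1L, mod])
        expect_gt(hi - lo, 0.4)
    }
})

test_that("noise-free coverage reproduces the block means exactly", {
    cfg <- simulationConfig(seed = 79, nMags = 8, nGroups = 2,
                            nMtSamples = 4, nMgSamples = 4, noiseCv = 0)
    cov <- generateCoverage(cfg)
    m <- cov$mt@coverage
    blocks <- cov$truth$mtBlock
    sblocks <- cov$truth$mtSampleBlock
    for (i in rownames(m)) for (j in colnames(m))
        expect_equal(m[i, j],
                     if (blocks[i] == sblocks[j]) 50 else 5)
})

test_that("the decoupled fraction is honoured exactly", {
    cfg <- simulationConfig(seed = 83, nMags = 20, nGroups = 4,
                            decoupledFraction = 0.2)
    cov <- generateCoverage(cfg)
    differing <- names(cov$truth$mtBlock)[
        cov$truth$mtBlock != cov$truth$mgBlock]
    expect_identical(length(differing), as.integer(ceiling(0.2 * 20)))
    expect_setequal(differing, cov$truth$decoupled)
})

test_that("generated metadata respects the constructive quality bounds", {
    cfg <- simulationConfig(seed = 89, nMags = 30, nExcludedOrder = 5,
                            nQualityFail = 6)
    meta <- generateMagMetadata(cfg)
    expect_identical(nrow(meta), 41L)
    passing <- meta[grepl("^MAG", meta$mag_id), ]
    expect_true(all(passing$completeness > 70))
    expect_true(all(passing$redundancy < 10))
    kept <- filterMags(meta)
    expect_identical(nrow(kept), 30L)
    # with no failing records the filter is the identity
    meta0 <- generateMagMetadata(simulationConfig(seed = 89, nMags = 30,
                                                  nExcludedOrder = 0))
    expect_identical(filterMags(meta0), meta0)
})

test_that("block coverage fixtures are recovered by Ward clustering", {
    aris <- vapply(1:10, function(s) {
        cfg <- simulationConfig(seed = 500 + s, nMags = 24, nGroups = 3,
                                nMtSamples = 6, noiseCv = 0.1,
                                blockSeparation = 10,
                                decoupledFraction = 0)
        cov <- generateCoverage(cfg)
        z <- zscoreRows(normalizeMagCoverage(cov$mt))
        part <- cutClusters(clusterRows(z), 3)
        mclust::adjustedRandIndex(part,
                                  cov$truth$mtBlock[names(part)])
    }, numeric(1))
    expect_gte(mean(aris), 0.9)
})

test_that("generators leave the caller's RNG stream untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(generateModuleDefinitions(simulationConfig(seed = 97,
                                                         nModules = 5)))
    expect_identical(.Random.seed, before)
})
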