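test_that("node completeness follows the recursive contract", {
    or <- parseModuleDefinition("Mx", "K00001,K00002")@root
    expect_equal(nodeCompleteness(or, "K00002"), 1)        # any sufficient
    expect_equal(nodeCompleteness(or, character(0)), 0)

    and <- parseModuleDefinition("Mx", "K00001+K00002")@root
    expect_equal(nodeCompleteness(and, "K00001"), 0.5)     # half the complex
    expect_equal(nodeCompleteness(and, c("K00001", "K00002")), 1)

    wild <- parseModuleDefinition("Mx", "K00001 --")@root
    expect_equal(nodeCompleteness(wild, character(0)), 0.5) # wildcard = 1
})

test_that("optional components never change a score", {
    with_opt <- parseModuleDefinition("Mx", "K00001-K00009 K00002")
    without <- parseModuleDefinition("Mx", "K00001 K00002")
    kosets <- list(character(0), "K00001", c("K00001", "K00002"),
                   c("K00001", "K00009"), c("K00001", "K00002", "K00009"))
    for (k in kosets)
        expect_equal(moduleCompletionScore(with_opt, k),
                     moduleCompletionScore(without, k),
                     label = paste(k, collapse = "+"))
})

test_that("MCS boundary semantics: full set scores 1, empty set scores 0", {
    m <- parseModuleDefinition("Mx", "(K00001,K00002) K00003+K00004 K00005")
    expect_identical(moduleCompletionScore(m, moduleKos(m)), 1)
    expect_identical(moduleCompletionScore(m, character(0)), 0)
    expect_identical(moduleCompletionScore(m, c("K99991", "K99992")), 0)
})

test_that("MCS averages per-step completeness over top-level steps only", {
    m <- parseModuleDefinition("Mx", "K00001 (K00002,K00003)")
    expect_equal(moduleCompletionScore(m, "K00001"), 0.5)
    # nested spaces contribute to their group's mean, not the step count
    m2 <- parseModuleDefinition("Mx", "(K00001 K00002) K00003")
    expect_equal(moduleCompletionScore(m2, "K00001"), 0.25)
    expect_equal(moduleCompletionScore(m2, c("K00001", "K00003")), 0.75)
})

test_that("recursive scorer equals the OR-expansion oracle on all subsets", {
    mods <- generateModuleDefinitions(simulationConfig(seed = 19,
                                                       nModules = 16))
    for (m in mods) {
        kos <- moduleKos(m)
        if (length(kos) > 10) next  # kept small here; full sweep elsewhere
        for (s in allSubsets(kos)) {
            expect_equal(moduleCompletionScore(m, s),
                         oracleModuleScore(m, s),
                         label = sprintf("%s with {%s}", m@sourceText,
                                         paste(s, collapse = ",")))
        }
    }
})

test_that("MCS is monotone under KO addition", {
    mods <- generateModuleDefinitions(simulationConfig(seed = 23,
                                                       nModules = 20))
    set.seed(101)
    for (m in mods) {
        kos <- moduleKos(m)
        for (r in 1:20) {
            small <- sample(kos, sample(0:length(kos), 1))
            extra <- union(small, sample(kos, sample(0:length(kos), 1)))
            expect_lte(moduleCompletionScore(m, small),
                       moduleCompletionScore(m, extra) + 1e-12)
        }
    }
})

test_that("computeMcsMatrix unions KO annotations per MAG", {
    mods <- list(parseModuleDefinition("M1", "K00001 K00002"),
                 parseModuleDefinition("M2", "K00003,K00004"))
    ann <- data.frame(
        orf_id = c("o1", "o2", "o3", "o4", "o5"),
        mag_id = c("magA", "magA", "magA", "magB", "magB"),
        ko_id = c("K00001", "K00002", "K00002", "K00003", "K00001"))
    mcs <- computeMcsMatrix(ann, mods)
    expect_s4_class(mcs, "MCSMatrix")
    expect_identical(magIds(mcs), c("magA", "magB"))
    expect_identical(moduleIds(mcs), c("M1", "M2"))
    expect_equal(scores(mcs)["magA", ], c(M1 = 1, M2 = 0))
    expect_equal(scores(mcs)["magB", ], c(M1 = 0.5, M2 = 1))
})

test_that("computeMcsMatrix fills absent modules with 0 and flags bad MAGs", {
    mods <- list(parseModuleDefinition("M1", "K00001"))
    ann <- data.frame(orf_id = "o1", mag_id = "magA", ko_id = "K00001")
    mcs <- computeMcsMatrix(ann, mods, magIds = c("magA", "magEmpty"))
    expect_equal(unname(scores(mcs)["magEmpty", ]), 0)
    expect_error(computeMcsMatrix(ann, mods, magIds = "magOther"),
                 "unknown MAG ids.*magA")
    expect_error(computeMcsMatrix(ann, list()), "non-empty")
})

test_that("every MCS lies in [0, 1] across random annotation tables", {
    mods <- generateModuleDefinitions(simulationConfig(seed = 29,
                                                       nModules = 12))
    kos <- unlist(lapply(mods, moduleKos))
    set.seed(73)
    for (r in 1:5) {
        n <- 60
        ann <- data.frame(orf_id = sprintf("o%d", 1:n),
                          mag_id = sample(c("m1", "m2", "m3"), n, TRUE),
                          ko_id = sample(kos, n, TRUE))
        s <- scores(computeMcsMatrix(ann, mods))
        expect_true(all(s >= 0 & s <= 1))
        expect_false(anyNA(s))
    }
})
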