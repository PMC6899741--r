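mkMg <- function(orfs, annos, hits, sample = "S1", total = 1e6) {
    ReadHitTable(sample, data.frame(orf_id = orfs, annotation_id = annos,
                                    hits = hits),
                 totalReads = total, assay = "metagenome")
}

mkMt <- function(orfs, annos, hits, sample = "S1", total = 1e6) {
    ReadHitTable(sample, data.frame(orf_id = orfs, annotation_id = annos,
                                    hits = hits),
                 totalReads = total, assay = "metatranscriptome")
}

test_that("read hits for ORFs sharing an annotation are averaged", {
    t <- mkMg(c("o1", "o2", "o3"), c("K00399", "K00399", "K00001"),
              c(10, 20, 7))
    expect_equal(meanHitsPerAnnotation(t, "K00399"), 15)
    expect_equal(meanHitsPerAnnotation(t, "K00001"), 7)
    expect_equal(meanHitsPerAnnotation(t, "K99999"), 0)
    # zero-hit ORFs are real observations
    t0 <- mkMg(c("o1", "o2"), c("K00001", "K00001"), c(10, 0))
    expect_equal(meanHitsPerAnnotation(t0, "K00001"), 5)
})

test_that("SCG normalization divides by the mean single-copy COG hits", {
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    t <- mkMg(c("g", sprintf("s%d", 1:35)),
              c("K00010", scg), c(10, rep(5, 35)))
    expect_equal(normalizeGeneAbundanceMg(t, "K00010", scg), 2)
    # absent gene
    expect_equal(normalizeGeneAbundanceMg(t, "K99999", scg), 0)
})

test_that("SCG normalization is invariant under uniform count scaling", {
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    set.seed(42)
    for (r in 1:20) {
        hits <- c(rpois(3, 40), rpois(35, 60) + 1)
        t1 <- mkMg(sprintf("o%d", 1:38),
                   c("K00010", "K00010", "K00011", scg), hits)
        t2 <- mkMg(sprintf("o%d", 1:38),
                   c("K00010", "K00010", "K00011", scg), hits * 17)
        v1 <- normalizeGeneAbundanceMg(t1, c("K00010", "K00011"), scg)
        v2 <- normalizeGeneAbundanceMg(t2, c("K00010", "K00011"), scg)
        expect_lt(abs(v1 - v2), 1e-9)
        expect_true(is.finite(v1))
    }
})

test_that("all-zero SCG hits raise a degenerate-denominator error", {
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    t <- mkMg(c("g", "s1"), c("K00010", "COG9001"), c(10, 0))
    expect_error(normalizeGeneAbundanceMg(t, "K00010", scg),
                 "degenerate denominator")
    tmt <- mkMt("g", "K00010", 10)
    expect_error(normalizeGeneAbundanceMg(tmt, "K00010", scg),
                 "metagenomic")
})

test_that("transcript abundance is hits over total reads", {
    t <- mkMt("g", "K00010", 100, total = 1e6)
    expect_equal(normalizeTranscriptAbundance(t, "K00010"), 1e-4)
    expect_equal(normalizeTranscriptAbundance(t, "K99999"), 0)
    # homogeneity: halving totals doubles the value, scaling hits scales it
    t2 <- mkMt("g", "K00010", 100, total = 5e5)
    expect_equal(normalizeTranscriptAbundance(t2, "K00010"), 2e-4)
    t3 <- mkMt("g", "K00010", 300, total = 1e6)
    expect_equal(normalizeTranscriptAbundance(t3, "K00010"), 3e-4)
})

test_that("abundance matrix agrees with the scalar operations", {
    catalog <- data.frame(category = "sulphur", gene_name = "soxB",
                          ko_ids = "K00010")
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    t <- mkMg(c("g", sprintf("s%d", 1:35)), c("K00010", scg),
              c(12, rep(4, 35)))
    ab <- buildAbundanceMatrix(list(t), catalog, scg)
    expect_identical(dim(values(ab)), c(1L, 1L))
    expect_equal(values(ab)["soxB", "S1"],
                 normalizeGeneAbundanceMg(t, "K00010", scg))
    expect_identical(assayType(ab), "metagenome")
})

test_that("genes absent from every sample give all-zero rows", {
    catalog <- data.frame(category = c("a", "b"),
                          gene_name = c("g1", "ghost"),
                          ko_ids = c("K00010", "K77777"))
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    tabs <- lapply(c("S1", "S2"), function(s)
        mkMg(c("g", sprintf("s%d", 1:35)), c("K00010", scg),
             c(8, rep(2, 35)), sample = s))
    ab <- buildAbundanceMatrix(tabs, catalog, scg)
    expect_equal(unname(values(ab)["ghost", ]), c(0, 0))
    expect_equal(unname(values(ab)["g1", ]), c(4, 4))
})

test_that("planted fold-differences between samples are recovered exactly", {
    cfg <- simulationConfig(seed = 31, nMgSamples = 5, nMtSamples = 4,
                            nGroups = 2)
    rh <- generateReadHits(cfg)
    abMg <- buildAbundanceMatrix(rh$mg, generateKeyGeneCatalog(),
                                 generateScgSet())
    expect_lt(max(abs(values(abMg) -
                      rh$truth$mgAbundance[entityIds(abMg), ])), 1e-9)
    abMt <- buildAbundanceMatrix(rh$mt, generateKeyGeneCatalog())
    expect_identical(abMt@displayScale, 1e6)
    expect_lt(max(abs(values(abMt) -
                      rh$truth$mtAbundance[entityIds(abMt), ])), 1e-9)
})

test_that("aggregation is independent of input row order", {
    scg <- singleCopyCogSet(sprintf("COG9%03d", 1:35))
    set.seed(7)
    orfs <- sprintf("o%d", 1:40)
    annos <- c(rep("K00010", 3), rep("K00011", 2), scg)
    hits <- c(rpois(5, 30), rpois(35, 50) + 1)
    perm <- sample(40)
    t1 <- mkMg(orfs, annos, hits)
    t2 <- mkMg(orfs[perm], annos[perm], hits[perm])
    expect_identical(
        normalizeGeneAbundanceMg(t1, c("K00010", "K00011"), scg),
        normalizeGeneAbundanceMg(t2, c("K00010", "K00011"), scg))
})

test_that("mixed assays in one matrix build are rejected", {
    catalog <- data.frame(category = "a", gene_name = "g1",
                          ko_ids = "K00010")
    t1 <- mkMg("g", "K00010", 5)
    t2 <- mkMt("g", "K00010", 5, sample = "S2")
    expect_error(buildAbundanceMatrix(list(t1, t2), catalog),
                 "one assay")
})
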