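mkRecords <- function() {
    data.frame(
        mag_id = sprintf("m%d", 1:6),
        order = c("Sulfurovum", "Pseudomonadales", "Sphingomonadales",
                  "Aquificales", "Methanococci", "Thiotrichales"),
        completeness = c(95, 92, 88, 70, 71, 99),
        redundancy = c(2, 1, 3, 5, 10, 9.9))
}

test_that("quality thresholds are strict and excluded orders are removed", {
    recs <- mkRecords()
    kept <- filterMags(recs)
    # m2/m3 excluded orders; m4 completeness == 70; m5 redundancy == 10
    expect_identical(kept$mag_id, c("m1", "m6"))
    # empty exclusion list: quality filtering only
    expect_identical(filterMags(recs, excludedOrders = character(0))$mag_id,
                     c("m1", "m2", "m3", "m6"))
    # idempotent and order-preserving
    expect_identical(filterMags(kept), kept)
    shuffled <- recs[c(4, 2, 6, 1, 3, 5), ]
    expect_setequal(filterMags(shuffled)$mag_id, kept$mag_id)
})

test_that("the study composition 73 bins minus 9 excluded orders gives 64", {
    meta <- generateMagMetadata(simulationConfig(seed = 1))
    expect_identical(nrow(meta), 73L)
    kept <- filterMags(meta)
    expect_identical(nrow(kept), 64L)
    expect_false(any(kept$order %in% c("Pseudomonadales",
                                       "Sphingomonadales")))
})

test_that("coverage normalization divides each column by its library size", {
    cov <- CoverageMatrix(
        matrix(c(50, 10, 20, 40), 2,
               dimnames = list(c("m1", "m2"), c("s1", "s2"))),
        c(s1 = 1e6, s2 = 2e6), "metatranscriptome")
    ab <- normalizeMagCoverage(cov)
    expect_equal(values(ab)["m1", "s1"], 5e-5)
    expect_equal(values(ab)["m2", "s2"], 2e-5)
    expect_identical(ab@normalization, "total_reads")

    # doubling one sample's total halves that column only
    cov2 <- CoverageMatrix(cov@coverage, c(s1 = 2e6, s2 = 2e6),
                           "metatranscriptome")
    ab2 <- normalizeMagCoverage(cov2)
    expect_equal(values(ab2)[, "s1"], values(ab)[, "s1"] / 2)
    expect_equal(values(ab2)[, "s2"], values(ab)[, "s2"])

    expect_error(normalizeMagCoverage(
        CoverageMatrix(cov@coverage, c(s1 = 1e6, s2 = 0),
                       "metatranscriptome")), "s2")
})

test_that("row z-scoring centres and scales with the n-1 denominator", {
    m <- matrix(c(1, 2, 3, 4, 4, 4), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
    z <- zscoreRows(m)
    expect_equal(unname(values(z)["a", ]), c(-1, 0, 1))
    expect_equal(unname(values(z)["b", ]), c(0, 0, 0))
    expect_identical(constantRows(z), "b")
    expect_error(zscoreRows(m[, 1, drop = FALSE]), "2 columns")
})

test_that("z-scoring is idempotent on non-constant rows", {
    set.seed(5)
    m <- matrix(rnorm(60), 6,
                dimnames = list(sprintf("r%d", 1:6), sprintf("s%d", 1:10)))
    z1 <- values(zscoreRows(m))
    z2 <- values(zscoreRows(z1))
    expect_lt(max(abs(z1 - z2)), 1e-9)
    expect_lt(max(abs(rowMeans(z1))), 1e-9)
    expect_lt(max(abs(apply(z1, 1, sd) - 1)), 1e-9)
})

test_that("identical rows merge first at height zero", {
    m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(9, 9, 9),
               d = c(-7, 5, 3))
    colnames(m) <- sprintf("s%d", 1:3)
    cl <- clusterRows(m)
    hc <- cl@hc
    expect_equal(hc$height[1], 0)
    first <- sort(hc$labels[-hc$merge[1, ]])
    expect_identical(first, c("a", "b"))
})

test_that("well-separated planted pairs stay adjacent in the leaf order", {
    m <- rbind(a = c(10, 10, 0.1), a2 = c(10.2, 9.9, 0.12),
               b = c(-5, 0.3, 8), b2 = c(-5.1, 0.28, 8.1))
    colnames(m) <- sprintf("s%d", 1:3)
    lo <- leafOrder(clusterRows(m))
    pos <- match(c("a", "a2", "b", "b2"), lo)
    expect_equal(abs(pos[1] - pos[2]), 1)
    expect_equal(abs(pos[3] - pos[4]), 1)
})

test_that("clustering is invariant to row permutation up to relabeling", {
    set.seed(9)
    m <- matrix(rnorm(48), 8,
                dimnames = list(sprintf("r%d", 1:8), sprintf("s%d", 1:6)))
    cl1 <- clusterRows(m)
    cl2 <- clusterRows(m[sample(8), ])
    expect_equal(sort(cl1@hc$height), sort(cl2@hc$height))
    p1 <- cutClusters(cl1, 3)
    p2 <- cutClusters(cl2, 3)[names(p1)]
    expect_equal(mclust::adjustedRandIndex(p1, p2), 1)
    expect_error(clusterRows(m[1, , drop = FALSE]), "at least 2")
})

test_that("column clustering works on the transposed axis", {
    set.seed(12)
    m <- matrix(rnorm(40), 4,
                dimnames = list(sprintf("r%d", 1:4), sprintf("s%d", 1:10)))
    cl <- clusterRows(m, axis = "columns")
    expect_setequal(leafOrder(cl), colnames(m))
})

test_that("applyClusterOrder reorders one matrix by another's dendrogram", {
    set.seed(3)
    m <- matrix(rnorm(30), 6,
                dimnames = list(sprintf("r%d", 1:6), sprintf("s%d", 1:5)))
    cl <- clusterRows(m)
    other <- matrix(seq_len(30), 6,
                    dimnames = list(sprintf("r%d", 1:6),
                                    sprintf("s%d", 1:5)))
    re <- applyClusterOrder(other, rowOrder = cl)
    expect_identical(rownames(re), leafOrder(cl))
    expect_identical(re["r3", ], other["r3", ])
})

test_that("koPresenceQuery reports supporting ORFs per MAG", {
    ann <- data.frame(orf_id = c("o1", "o2", "o3"),
                      mag_id = c("magA", "magA", "magB"),
                      ko_id = c("K00399", "K00399", "K00001"))
    q <- koPresenceQuery(ann, c("K00399", "K00001"))
    mcrA_A <- q[q$mag_id == "magA" & q$ko_id == "K00399", ]
    expect_true(mcrA_A$present)
    expect_identical(mcrA_A$orf_ids, "o1,o2")
    mcrA_B <- q[q$mag_id == "magB" & q$ko_id == "K00399", ]
    expect_false(mcrA_B$present)
    expect_identical(mcrA_B$orf_ids, "")
    # empty table: all absent
    empty <- koPresenceQuery(ann[0, ], "K00399", magIds = "magA")
    expect_false(any(empty$present))
})
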