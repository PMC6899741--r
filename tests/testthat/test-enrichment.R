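test_that("Mann-Whitney U matches hand-derived small cases", {
    r <- mannWhitneyU(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))
    expect_equal(r$u, 9)
    expect_equal(r$p, 0.1)
    expect_true(r$exact)

    r2 <- mannWhitneyU(0.5, 0.5)
    expect_equal(r2$p, 1)

    expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("swapping groups complements U and preserves p", {
    set.seed(17)
    for (r in 1:25) {
        a <- round(runif(sample(2:9, 1)), 3)
        b <- round(runif(sample(2:9, 1)), 3)
        f <- mannWhitneyU(a, b)
        g <- mannWhitneyU(b, a)
        expect_equal(f$u + g$u, length(a) * length(b))
        expect_equal(f$p, g$p)
    }
})

test_that("exact p-values agree with assignment enumeration for n <= 8", {
    set.seed(29)
    for (r in 1:60) {
        na <- sample(2:8, 1); nb <- sample(2:8, 1)
        pooled <- sample(1000, na + nb)   # untied by construction
        a <- pooled[seq_len(na)]; b <- pooled[-seq_len(na)]
        got <- mannWhitneyU(a, b)
        expect_true(got$exact)
        expect_equal(got$p, oracleExactMwu(a, b), tolerance = 1e-12,
                     label = sprintf("n=(%d,%d) rep %d", na, nb, r))
    }
})

test_that("normal approximation tracks the exact test on untied samples", {
    set.seed(37)
    diffs <- replicate(200, {
        n <- sample(3:8, 2, replace = TRUE)
        pooled <- sample(1e6, sum(n))
        a <- pooled[seq_len(n[1])]; b <- pooled[-seq_len(n[1])]
        abs(mannWhitneyU(a, b, exact = TRUE)$p -
            mannWhitneyU(a, b, exact = FALSE)$p)
    })
    expect_lt(max(diffs), 0.06)
    expect_lt(mean(diffs), 0.02)
})

test_that("expression groups are assigned by argmax transcript abundance", {
    vals <- rbind(
        magP = c(5, 6, 0, 0),    # expressed only at Piccard samples
        magV = c(0, 0, 4, 9),
        magZ = c(0, 0, 0, 0))    # no signal: excluded
    colnames(vals) <- sprintf("MT%02d", 1:4)
    ab <- new("AbundanceMatrix", values = vals,
              assay = "metatranscriptome", normalization = "total_reads",
              displayScale = 1)
    si <- data.frame(sample_id = colnames(vals),
                     site = c("s1", "s2", "s3", "s4"),
                     field = c("Piccard", "Piccard", "VonDamm", "VonDamm"))
    g <- assignExpressionGroups(ab, si, "field", "Piccard")
    expect_identical(groupMembers(g, "A"), "magP")
    expect_identical(groupMembers(g, "B"), "magV")
    expect_identical(g@excluded, "magZ")
    expect_error(assignExpressionGroups(ab, si, "field", "Atlantis"),
                 "unknown focal")
})

test_that("planted site-exclusive expression is assigned perfectly", {
    cfg <- simulationConfig(seed = 41, nMags = 20, nGroups = 2,
                            nMtSamples = 6, noiseCv = 0.1,
                            decoupledFraction = 0)
    cov <- generateCoverage(cfg)
    ab <- normalizeMagCoverage(cov$mt)
    si <- cov$samples[cov$samples$assay == "metatranscriptome", ]
    g <- assignExpressionGroups(ab, si, "site", "site1")
    expected <- names(cov$truth$mtBlock)[cov$truth$mtBlock == 1L]
    expect_setequal(groupMembers(g, "A"), expected)
})

test_that("per-module enrichment flags planted completion shifts", {
    mods <- sprintf("M%02d", 1:6)
    mags <- sprintf("mag%02d", 1:20)
    set.seed(53)
    s <- matrix(runif(120, 0.3, 0.7), 20, dimnames = list(mags, mods))
    # plant a strong shift in M01: group A near-complete, group B depleted
    groupA <- mags[1:10]; groupB <- mags[11:20]
    s[groupA, "M01"] <- runif(10, 0.9, 1)
    s[groupB, "M01"] <- runif(10, 0, 0.1)
    mcs <- new("MCSMatrix", scores = s)
    g <- new("MagGrouping", groupA = groupA, groupB = groupB)
    res <- enrichModules(mcs, g)
    expect_identical(res$module_id[1], "M01")
    expect_lt(res$p[1], 1e-3)
    expect_identical(res$direction[1], "A_higher")
    expect_true(all(diff(res$p) >= 0))
    expect_true(all(res$u <= res$n_a * res$n_b))
})

test_that("identical group distributions give p = 1 and tied direction", {
    s <- matrix(0.5, 6, 1, dimnames = list(sprintf("m%d", 1:6), "M1"))
    mcs <- new("MCSMatrix", scores = s)
    g <- new("MagGrouping", groupA = sprintf("m%d", 1:3),
             groupB = sprintf("m%d", 4:6))
    res <- enrichModules(mcs, g)
    expect_equal(res$p, 1)
    expect_identical(res$direction, "tied")
})

test_that("enrichment validates its inputs", {
    s <- matrix(runif(8), 4, 2,
                dimnames = list(sprintf("m%d", 1:4), c("M1", "M2")))
    mcs <- new("MCSMatrix", scores = s)
    g <- new("MagGrouping", groupA = c("m1", "ghost"), groupB = "m2")
    expect_error(enrichModules(mcs, g), "ghost")
    # benjamini-hochberg never decreases p
    g2 <- new("MagGrouping", groupA = c("m1", "m2"), groupB = c("m3", "m4"))
    raw <- enrichModules(mcs, g2)
    adj <- enrichModules(mcs, g2, correction = "benjamini_hochberg")
    expect_true(all(adj$p_adj >= raw$p - 1e-12))
})
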