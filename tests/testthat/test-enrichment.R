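test_that("window overlap handles boundaries exactly", {
    cpgs <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr1",
        pos = c(1000, 1000, 1000))
    # [1099,1200) touches the window's last base; [1100,.) does not;
    # [1101,.) is clearly out
    peaks <- data.frame(chrom = "chr1",
        start = c(1099, 1100, 1101), end = c(1200, 1200, 1200))
    expect_true(windowPeakOverlap(cpgs[1, ], peaks[1, , drop = FALSE]))
    expect_false(unname(windowPeakOverlap(cpgs[1, ],
        peaks[2, , drop = FALSE])))
    expect_false(unname(windowPeakOverlap(cpgs[1, ],
        peaks[3, , drop = FALSE])))
    # left edge: window starts at pos - 100 (0-based)
    left <- data.frame(chrom = "chr1", start = c(899, 850), end = c(950, 900))
    expect_true(unname(windowPeakOverlap(cpgs[1, ],
        left[1, , drop = FALSE])))
    expect_false(unname(windowPeakOverlap(cpgs[1, ],
        left[2, , drop = FALSE])))
    expect_error(windowPeakOverlap(cpgs, peaks, window = 201), "even")
    expect_warning(windowPeakOverlap(data.frame(cpg_id = "z",
        chrom = "chrZ", pos = 5000), peaks), "without peaks")
})

test_that("window overlap equals the quadratic all-pairs oracle", {
    set.seed(14)
    for (rep in 1:5) {
        cpgs <- data.frame(cpg_id = paste0("cg", 1:400),
            chrom = sample(c("chr1", "chr2"), 400, TRUE),
            pos = sample.int(50000, 400))
        peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
            start = s <- sample.int(50000, 300),
            end = s + sample.int(400, 300))
        got <- suppressWarnings(windowPeakOverlap(cpgs, peaks))
        expect_identical(unname(got), overlapOracle(cpgs, peaks))
    }
    # translation invariance
    cpgs <- data.frame(cpg_id = "a", chrom = "chr1", pos = 1000)
    peaks <- data.frame(chrom = "chr1", start = 1050, end = 1120)
    shift <- 12345
    expect_identical(
        unname(windowPeakOverlap(cpgs, peaks)),
        unname(windowPeakOverlap(transform(cpgs, pos = pos + shift),
            transform(peaks, start = start + shift,
                end = end + shift))))
})

test_that("hypergeometric enrichment equals direct tail summation", {
    expect_equal(hypergeometricEnrichment(100, 20, 100, 20), 1)
    expect_equal(hypergeometricEnrichment(100, 20, 10, 8),
        hypergeomTailOracle(100, 20, 10, 8), tolerance = 1e-12)
    expect_equal(hypergeometricEnrichment(50, 0, 10, 0), 1)
    set.seed(15)
    for (i in 1:200) {
        N <- sample(10:10000, 1)
        K <- sample.int(N, 1)
        n <- sample.int(N, 1)
        x <- sample(0:min(n, K), 1)
        expect_equal(hypergeometricEnrichment(N, K, n, x),
            hypergeomTailOracle(N, K, n, x), tolerance = 1e-9)
    }
    expect_error(hypergeometricEnrichment(10, 20, 5, 2), "inconsistent")
})

test_that("probe-bias resampling null behaves as designed", {
    set.seed(16)
    genes <- paste0("G", 1:200)
    # equal probe counts: one CpG per gene
    ann <- data.frame(cpg_id = paste0("cg", 1:200), gene_symbols = genes)
    sets <- list(S1 = genes[1:40], S2 = genes[41:200])
    sig <- paste0("cg", sample.int(200, 30))
    res <- probeBiasGenesetTest(sig, ann$cpg_id, ann, sets,
        nResamples = 20000, seed = 1)
    # with equal probe counts the null is plain hypergeometric
    obs <- res$observed_hits[res$set == "S1"]
    pHyper <- hypergeometricEnrichment(200, 40, 30, obs)
    expect_lt(abs(res$p_value[res$set == "S1"] - pHyper),
        3 * sqrt(pHyper * (1 - pHyper) / 20000) + 1e-3)

    # a gene with 10x probes is drawn ~10x as often into the null
    ann2 <- data.frame(
        cpg_id = paste0("cg", 1:210),
        gene_symbols = c(rep("BIG", 10), paste0("G", 1:200)))
    sigCpgs <- paste0("cg", 11:15)   # 5 hit genes, BIG not among them
    res2 <- probeBiasGenesetTest(sigCpgs, ann2$cpg_id, ann2,
        list(BIGSET = "BIG", OTHER = paste0("G", 150:200)),
        nResamples = 20000, seed = 2)
    # per-gene inclusion probability in the null is proportional to the
    # probe count while the draw stays small, so the 10x-probe gene is
    # selected ~10x as often as a single-probe gene
    pBig <- res2$expected_hits[res2$set == "BIGSET"]
    pSmall <- res2$expected_hits[res2$set == "OTHER"] / 51
    expect_gt(pBig / pSmall, 7)
    expect_lt(pBig / pSmall, 13)

    # planted enrichment is detected, unplanted sets stay null
    set.seed(17)
    sig3 <- paste0("cg", c(1:25, sample(26:200, 10)))
    res3 <- probeBiasGenesetTest(sig3, ann$cpg_id, ann,
        list(planted = genes[1:30], other = genes[101:200]),
        nResamples = 5000, seed = 3)
    expect_lt(res3$p_value[res3$set == "planted"], 0.01)
    expect_gt(res3$p_value[res3$set == "other"], 0.05)
    expect_warning(probeBiasGenesetTest(sig3, ann$cpg_id, ann,
        list(empty = "NOT_A_GENE", ok = genes[1:5]), nResamples = 10,
        seed = 1), "skipping")
    # reproducible under a fixed seed
    a <- probeBiasGenesetTest(sig3, ann$cpg_id, ann, sets,
        nResamples = 500, seed = 9)
    b <- probeBiasGenesetTest(sig3, ann$cpg_id, ann, sets,
        nResamples = 500, seed = 9)
    expect_identical(a$p_value, b$p_value)
})

test_that("list overlap test restricts the universe and matches Fisher", {
    uni <- paste0("cg", 1:2600)
    sel <- uni[1:207]
    pub <- c(uni[200:291])
    res <- listOverlapTest(sel, pub, uni)
    expect_equal(res$overlap, 8)
    ft <- fisher.test(matrix(c(8, 199, 84, 2309), 2, byrow = TRUE))
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
    # selected = universe makes every list fully overlap at p = 1
    res2 <- listOverlapTest(uni, pub, uni)
    expect_equal(res2$overlap, length(pub))
    expect_equal(res2$p_value, 1)
    # platform restriction shrinks the universe before testing
    res3 <- listOverlapTest(sel, pub, uni, restrictTo = uni[1:300])
    expect_equal(res3$table["selected", "published"],
        length(intersect(sel[1:207], pub[pub %in% uni[1:300]])))
    expect_error(listOverlapTest(sel, "zz", uni), "disjoint")
    # independence: p roughly uniform over repeated random selections
    set.seed(18)
    ps <- replicate(300, {
        s <- sample(uni, 300)
        p <- sample(uni, 100)
        listOverlapTest(s, p, uni)$p_value
    })
    expect_gt(mean(ps > 0.5), 0.35)
    expect_lt(mean(ps < 0.05), 0.1)
})
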