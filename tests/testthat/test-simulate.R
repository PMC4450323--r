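test_that("genetic simulation follows the generative model", {
    cfg <- SimulationConfig(nPatients = 4, nVariants = 20, seed = 101)
    sim <- simulateGeneticCohort(cfg,
        categories = c("static", "evolving", "expanding", "static"))
    # identical seeds give bit-identical output
    sim2 <- simulateGeneticCohort(cfg,
        categories = c("static", "evolving", "expanding", "static"))
    expect_identical(as.data.frame(sim$amplicon),
        as.data.frame(sim2$amplicon))
    expect_identical(sim$truth$true_category, sim2$truth$true_category)
    # counts are non-negative integers with positive depth
    a <- as.data.frame(sim$amplicon)
    cnt <- as.matrix(a[, grep("count", names(a))])
    expect_true(all(cnt >= 0 & cnt == round(cnt)))
    expect_true(all(a$ref_count_g + a$alt_count_g > 0))
    # identical clone fractions and purity mean no true drift
    expect_true(all(sim$truth$true_drift_directions[
        paste0("P01_s", sprintf("%03d", 1:20))] == "none"))
    # planted categories appear in the truth
    expect_equal(unname(sim$truth$true_category),
        c("static", "evolving", "expanding", "static"))
    # germline sites carry het/hom structure in all samples
    g <- a[grepl("_g", a$site_id), ]
    gaf <- g$alt_count_g / (g$ref_count_g + g$alt_count_g)
    expect_true(any(gaf > 0.9))
    expect_true(any(abs(gaf - 0.5) < 0.2))
    expect_error(simulateGeneticCohort(
        SimulationConfig(depthAmplicon = 0)), "positive")
})

test_that("empirical VAFs converge to the generative expectation", {
    # a clone rising 0.2 -> 0.8 at purity 1: VAF 0.10 -> 0.40, so the
    # mean simulated VAF difference over replicates is 0.30 within the
    # binomial standard error
    set.seed(55)
    nRep <- 1000
    depth <- 850
    d1 <- rbinom(nRep, depth, 0.10) / depth
    d2 <- rbinom(nRep, depth, 0.40) / depth
    se <- sqrt((0.1 * 0.9 + 0.4 * 0.6) / depth / nRep)
    expect_lt(abs(mean(d2 - d1) - 0.30), 3 * se)
    # the same expectation through the simulator at high depth
    cs <- CloneStructure("P", c(0.2, 0), c(0.8, 0), c(1L, 2L),
        purityT1 = 1, purityT2 = 1)
    ev <- expectedVAF(cs)
    expect_equal(unname(ev[1, ]), c(0.10, 0.40))
    cfg <- SimulationConfig(nPatients = 1, nVariants = 25,
        depthAmplicon = 1e5, seed = 77)
    sim <- simulateGeneticCohort(cfg, categories = "expanding",
        prevalenceShift = 0.3, nClones = 2)
    a <- as.data.frame(sim$amplicon)
    som <- a[grepl("_s", a$site_id), ]
    csP <- sim$truth$clone_structures$P01
    evP <- expectedVAF(csP)
    emp2 <- som$alt_count_t2 / (som$ref_count_t2 + som$alt_count_t2)
    expect_lt(max(abs(emp2 - evP[, "t2"])), 0.01)  # LLN at depth 1e5
})

test_that("methylation simulation plants what it claims", {
    cfg <- SimulationConfig(nPatients = 6, nCpgs = 800, noiseSd = 0,
        fracProgressionCpgs = 0.05, seed = 42)
    sim <- simulateMethylationCohort(cfg)
    b <- betaValues(sim$beta)
    expect_true(all(b >= 0 & b <= 1))
    # determinism
    sim2 <- simulateMethylationCohort(cfg)
    expect_identical(betaValues(sim2$beta), b)
    # planted CpGs move by exactly the planted effect when noise is off
    # and composition is held fixed; here compositions differ between
    # timepoints, so verify against the constructed means instead
    W <- sim$truth$true_compositions
    prof <- sim$profiles
    eff <- sim$truth$true_effects
    i <- names(eff)[1]
    p1 <- sum(prof[i, ] * W["P01_t1", ])
    p2 <- sum(prof[i, ] * W["P01_t2", ]) + eff[1]
    expect_equal(unname(b[i, "P01_t1"]), unname(min(1, max(0, p1))),
        tolerance = 1e-12)
    expect_equal(unname(b[i, "P01_t2"]), unname(min(1, max(0, p2))),
        tolerance = 1e-12)
    # a pure B-cell sample with no noise equals the B reference column
    panel <- sim$panel
    R <- profileMatrix(panel)
    w <- proportions(deconvolve(R[, "B"], panel))
    expect_equal(unname(w[1, "B"]), 1, tolerance = 1e-8)
    # effect magnitudes respect the configured range and median
    expect_true(all(abs(eff) >= cfg@effectMin - 1e-12))
    expect_true(all(abs(eff) <= cfg@effectMax + 1e-12))
})

test_that("planted direction and flag enrichment match their settings", {
    cfg <- SimulationConfig(nPatients = 4, nCpgs = 20000,
        fracProgressionCpgs = 0.05, seed = 4)
    sim <- simulateMethylationCohort(cfg)
    eff <- sim$truth$true_effects
    # 77% increases within binomial error (n = 1000 planted)
    n <- length(eff)
    expect_equal(n, 1000)
    se <- sqrt(0.77 * 0.23 / n)
    expect_lt(abs(mean(eff > 0) - 0.77), 3 * se)
    # planted effect median near 0.029
    expect_lt(abs(median(abs(eff)) - 0.029), 0.006)
    # H3K27me3 flags enriched at planted CpGs near the configured OR
    ann <- sim$annotation
    flag <- setNames(ann$h3k27me3_flag, ann$cpg_id)
    planted <- names(eff)
    a <- sum(flag[planted]); b <- sum(!flag[planted])
    cc <- sum(flag[setdiff(ann$cpg_id, planted)])
    d <- sum(!flag[setdiff(ann$cpg_id, planted)])
    orEst <- (a * d) / (b * cc)
    expect_gt(orEst, 2)
    expect_lt(orEst, 4.5)
    # synthetic peaks reproduce the flags through window overlap
    got <- suppressWarnings(windowPeakOverlap(ann, sim$peaks))
    expect_identical(unname(got), unname(flag))
})

test_that("B-cell reference panels carry the planted concordance", {
    cfg <- SimulationConfig(nPatients = 6, nCpgs = 1000,
        fracProgressionCpgs = 0.05, seed = 12)
    sim <- simulateMethylationCohort(cfg)
    bc <- simulateBCellPanels(sim, seed = 13, concordantFrac = 1)
    eff <- sim$truth$true_effects
    mN <- rowMeans(betaValues(bc$naive))[names(eff)]
    mM <- rowMeans(betaValues(bc$memory))[names(eff)]
    # naive-to-memory difference runs in the planted direction
    agree <- sign(mM - mN) == sign(eff)
    expect_gt(mean(agree), 0.9)
})
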