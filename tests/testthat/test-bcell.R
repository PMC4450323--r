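makeGroupBM <- function(mu, n, label) {
    m <- matrix(rep(mu, n), length(mu), n,
        dimnames = list(names(mu), paste0(label, seq_len(n))))
    BetaMatrix(m, patientId = colnames(m), timepoint = NA, group = label)
}

test_that("groupwise deltas flag 10% differences with correct signs", {
    cg <- paste0("cg", 1:4)
    naive <- makeGroupBM(setNames(c(0.20, 0.50, 0.50, 0.30), cg), 6, "n")
    memory <- makeGroupBM(setNames(c(0.35, 0.50, 0.45, 0.10), cg), 6, "m")
    cll <- makeGroupBM(setNames(c(0.35, 0.50, 0.70, 0.30), cg), 3, "c")
    gd <- groupwiseDeltas(naive, memory, cll)
    expect_equal(gd$delta_naive_memory, c(0.15, 0, -0.05, -0.20))
    expect_equal(gd$flag_naive_memory, c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(gd$delta_naive_cll1, c(0.15, 0, 0.20, 0))
    expect_equal(gd$delta_memory_cll1, c(0, 0, 0.25, 0.20))
    # identical group means: nothing flagged
    gd0 <- groupwiseDeltas(naive, naive, makeGroupBM(
        setNames(c(0.20, 0.50, 0.50, 0.30), cg), 2, "x"))
    expect_false(any(gd0$flag_naive_memory))
    # antisymmetry: swapping groups negates deltas, keeps flags
    gdSwap <- groupwiseDeltas(memory, naive, cll)
    expect_equal(gdSwap$delta_naive_memory, -gd$delta_naive_memory)
    expect_equal(gdSwap$flag_naive_memory, gd$flag_naive_memory)
    expect_error(groupwiseDeltas(naive[, 0], memory, cll), "empty")
})

test_that("three-way overlap enrichment detects planted structure", {
    set.seed(21)
    n <- 1000
    cg <- paste0("cg", seq_len(n))
    differing <- cg[1:200]
    d <- setNames(rep(0, n), cg)
    d[differing] <- 0.2
    comparison <- S4Vectors::DataFrame(cpg_id = cg,
        delta_naive_memory = unname(d), delta_naive_cll1 = unname(d),
        delta_memory_cll1 = 0,
        flag_naive_memory = unname(d) >= 0.1,
        flag_naive_cll1 = unname(d) >= 0.1,
        flag_memory_cll1 = FALSE,
        dir_naive_memory = sign(unname(d)),
        dir_naive_cll1 = sign(unname(d)), dir_memory_cll1 = 0)
    # planted 3x over-representation of the progression set
    prog <- c(sample(differing, 90), sample(cg[201:1000], 60))
    res <- suppressWarnings(overlapEnrichmentThreeWay(comparison, prog))
    p1 <- res$p_value[res$pair == "naive_memory" & res$stratum == "all"]
    expect_lt(p1, 0.01)
    # a uniformly drawn set is not enriched
    res0 <- suppressWarnings(overlapEnrichmentThreeWay(comparison,
        sample(cg, 150)))
    expect_gt(res0$p_value[res0$pair == "naive_memory" &
        res0$stratum == "all"], 0.01)
    # progression set equal to the differing set: minimal achievable p
    resMax <- suppressWarnings(overlapEnrichmentThreeWay(comparison,
        differing))
    expect_equal(
        resMax$p_value[resMax$pair == "naive_memory" &
            resMax$stratum == "all"],
        hypergeometricEnrichment(n, 200, 200, 200))
    # empty differing set warns and returns p = 1
    comparison$flag_memory_cll1 <- FALSE
    expect_warning(resE <- overlapEnrichmentThreeWay(comparison, prog),
        "no CpGs differ")
    expect_true(all(resE$p_value[resE$pair == "memory_cll1"] == 1))
})

test_that("direction concordance behaves at both extremes", {
    cg <- paste0("cg", 1:400)
    comparison <- S4Vectors::DataFrame(cpg_id = cg,
        delta_naive_memory = rep(0.2, 400),
        delta_naive_cll1 = 0.2, delta_memory_cll1 = 0.2,
        flag_naive_memory = TRUE, flag_naive_cll1 = TRUE,
        flag_memory_cll1 = TRUE,
        dir_naive_memory = 1, dir_naive_cll1 = 1, dir_memory_cll1 = 1)
    prog <- setNames(rep(0.1, 400), cg)
    res <- directionConcordance(prog, comparison, "naive_memory")
    expect_equal(res$pct_same_direction, 100)
    # independent random signs sit at 50% within binomial error
    set.seed(22)
    prog2 <- setNames(sample(c(-0.1, 0.1), 400, TRUE), cg)
    res2 <- directionConcordance(prog2, comparison, "naive_memory")
    expect_lt(abs(res2$pct_same_direction - 50),
        3 * 100 * sqrt(0.25 / 400))
    # zero deltas drop out of the denominator
    prog3 <- setNames(c(rep(0, 399), 0.1), cg)
    res3 <- directionConcordance(prog3, comparison, "naive_memory")
    expect_equal(res3$n_overlap, 1L)
    # empty overlap is undefined
    expect_warning(res4 <- directionConcordance(
        setNames(numeric(0), character(0)), comparison, "naive_memory"),
        "empty overlap")
    expect_true(is.na(res4$pct_same_direction))
})

test_that("similarity clustering places CLL nearest memory by construction", {
    set.seed(23)
    cfg <- SimulationConfig(nPatients = 5, nCpgs = 600,
        fracProgressionCpgs = 0.05, seed = 24)
    sim <- simulateMethylationCohort(cfg)
    bc <- simulateBCellPanels(sim, seed = 25)
    # CLL-like profiles built as memory + small progression deltas
    mem <- rowMeans(betaValues(bc$memory))
    prog <- sim$truth$true_progression_cpgs
    S <- vapply(1:4, function(i) {
        x <- mem
        x[prog] <- pmin(1, pmax(0, x[prog] +
            sim$truth$true_effects * 0.5))
        pmin(1, pmax(0, x + rnorm(length(x), 0, 0.01)))
    }, numeric(length(mem)))
    dimnames(S) <- list(names(mem), paste0("CLL", 1:4))
    cll <- BetaMatrix(S, patientId = colnames(S), timepoint = NA)
    res <- similarityClustering(cll, bc$naive, bc$memory, cpgs = prog)
    expect_true(all(res$nearest$nearest == "memory"))
    expect_s3_class(res$tree, "phylo")
    expect_false(res$degenerate)
    # sample-order invariance of the nearest calls
    res2 <- similarityClustering(cll[, 4:1], bc$naive, bc$memory,
        cpgs = prog)
    expect_identical(sort(res2$nearest$sample_id),
        sort(res$nearest$sample_id))
    expect_true(all(res2$nearest$nearest == "memory"))
    # identical samples merge at height zero
    two <- cll[, c(1, 1)]
    colnames(two) <- c("A", "B")
    resT <- similarityClustering(two, bc$naive, bc$memory)
    expect_equal(min(resT$hclust$height), 0)
})
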