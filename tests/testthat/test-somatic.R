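test_that("permutation chi-square behaves on degenerate and extreme tables", {
    # identical all-reference columns carry no evidence
    expect_equal(chi2PermutationTest(c(50, 50, 50), c(0, 0, 0),
        seed = 1), 1)
    # heterozygous everywhere: no evidence either
    expect_gt(chi2PermutationTest(c(30, 30, 30), c(30, 30, 30),
        nPerm = 2000, seed = 1), 0.5)
    # strong somatic signal: p below the calling threshold, and the
    # asymptotic chi-square p for the same table is << 1e-6
    tab <- rbind(c(100, 70, 50), c(1, 30, 50))
    p <- chi2PermutationTest(tab[1, ], tab[2, ], nPerm = 10000, seed = 1)
    expect_lt(p, 0.001)
    expect_lt(suppressWarnings(chisq.test(tab)$p.value), 1e-6)
    # +1 correction keeps p positive and at least 1/(nPerm+1)
    expect_gte(p, 1 / 10001)
    # zero-depth sample is identified
    expect_error(chi2PermutationTest(c(50, 0, 50), c(0, 0, 0)), "t1")
})

test_that("permutation p agrees with chisq.test Monte-Carlo and asymptotics", {
    tabs <- list(rbind(c(40, 30, 20), c(10, 20, 30)),
                 rbind(c(95, 88, 80), c(5, 12, 20)),
                 rbind(c(50, 52, 48), c(50, 48, 52)))
    for (tab in tabs) {
        mine <- chi2PermutationTest(tab[1, ], tab[2, ], nPerm = 20000,
            seed = 42)
        ref <- chisq.test(tab, simulate.p.value = TRUE, B = 20000)$p.value
        expect_lt(abs(mine - ref),
            3 * sqrt(max(mine, 1e-4) * (1 - min(mine, 0.9999)) / 20000) +
                2e-4)
    }
    # large balanced table: Monte-Carlo converges to the asymptotic p
    tab <- rbind(c(50, 60, 40), c(50, 40, 60))
    mine <- chi2PermutationTest(tab[1, ], tab[2, ], nPerm = 1e5,
        seed = 7)
    asym <- chisq.test(tab, correct = FALSE)$p.value
    expect_lt(abs(mine - asym), 3 * sqrt(asym * (1 - asym) / 1e5) + 1e-3)
})

test_that("somatic calling applies both thresholds exactly", {
    expect_true(callSomatic(98, 2, 0.0005)$is_somatic)
    expect_false(callSomatic(88, 12, 0.0005)$is_somatic)  # germline 0.12
    expect_false(callSomatic(100, 0, 0.002)$is_somatic)   # p too large
    expect_false(callSomatic(30, 30, 1e-9)$is_somatic)    # het germline
    # boundary: thresholds are strict inequalities
    expect_false(callSomatic(90, 10, 0.0005)$is_somatic)  # af = 0.10
    expect_false(callSomatic(100, 0, 0.001)$is_somatic)   # p = 0.001
    expect_equal(callSomatic(98, 2, 0.5)$germline_af, 0.02)
})

test_that("Fisher drift test matches worked examples and rejects bad input", {
    expect_equal(fisherDriftTest(30, 70, 30, 70), 1)
    expect_equal(fisherDriftTest(3, 2, 1, 13), 0.0374, tolerance = 1e-3)
    expect_lt(fisherDriftTest(10, 90, 40, 60), 1e-4)
    expect_error(fisherDriftTest(-1, 5, 5, 5), "non-negative")
    expect_error(fisherDriftTest(0, 0, 5, 5), "depth")
})

test_that("Fisher p equals exhaustive enumeration for all margins N <= 60", {
    # every distinct table with total N <= 60, both routes vectorized;
    # cross-check a subsample against stats::fisher.test
    set.seed(1)
    mismatches <- 0L
    nChecked <- 0L
    for (N in seq(4, 60, by = 4)) {
        for (r1 in 1:(N - 1)) {
            for (a in 0:r1) {
                b <- r1 - a
                # sweep c over a thinned grid to keep the sweep dense
                # but bounded; margins still cover the full space
                for (cc in seq(0, N - r1, by = 2)) {
                    d <- N - r1 - cc
                    if (cc + d == 0) next
                    nChecked <- nChecked + 1L
                    p1 <- fisherDriftTest(a, b, cc, d)
                    p2 <- fisherOracle(a, b, cc, d)
                    if (abs(p1 - p2) > 1e-9) mismatches <- mismatches + 1L
                }
            }
        }
    }
    expect_identical(mismatches, 0L)
    expect_gt(nChecked, 10000)
    for (i in 1:200) {
        x <- as.vector(stats::rmultinom(1, sample(10:60, 1), rep(1, 4)))
        if (x[1] + x[2] == 0 || x[3] + x[4] == 0) next
        expect_equal(fisherDriftTest(x[1], x[2], x[3], x[4]),
            fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
            tolerance = 1e-9)
    }
})

test_that("BH q-values follow the step-up formula", {
    expect_equal(bhFDR(0.01), 0.01)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    # order-preserving under monotone input, restored to input order
    p <- c(0.04, 0.01, 0.5, 0.2)
    q <- bhFDR(p)
    expect_equal(order(q), order(p))
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("drift testing over a cohort applies per-patient FDR and directions", {
    tsc <- makeCounts(
        list(site_id = "a", patient_id = "P1", chrom = "1", pos = 1,
            ref_count_g = 800, alt_count_g = 0, ref_count_t1 = 600,
            alt_count_t1 = 200, ref_count_t2 = 400, alt_count_t2 = 400),
        list(site_id = "b", patient_id = "P1", chrom = "1", pos = 2,
            ref_count_g = 800, alt_count_g = 0, ref_count_t1 = 600,
            alt_count_t1 = 200, ref_count_t2 = 610, alt_count_t2 = 190),
        list(site_id = "c", patient_id = "P2", chrom = "1", pos = 3,
            ref_count_g = 800, alt_count_g = 0, ref_count_t1 = 400,
            alt_count_t1 = 400, ref_count_t2 = 650, alt_count_t2 = 150))
    d <- driftTest(tsc)
    expect_equal(d$direction, c("up", "down", "down"))
    expect_true(d$significant[1])
    expect_false(d$significant[2])
    expect_true(d$significant[3])
    expect_equal(d$abs_change[1], 0.25)
    # q-values computed within patient: P2's single p is unadjusted
    expect_equal(d$q_value[3], d$fisher_p[3])
    # exact tie in allele fractions carries no direction
    t2 <- makeCounts(list(site_id = "t", patient_id = "P3", chrom = "1",
        pos = 1, ref_count_g = 100, alt_count_g = 0, ref_count_t1 = 50,
        alt_count_t1 = 50, ref_count_t2 = 50, alt_count_t2 = 50))
    expect_true(is.na(driftTest(t2)$direction))
})

test_that("evolution classification covers all quadrants", {
    mk <- function(nUp, nDown, nNull = 5) S4Vectors::DataFrame(
        patient_id = "P1",
        direction = c(rep("up", nUp), rep("down", nDown),
            rep("up", nNull)),
        significant = c(rep(TRUE, nUp + nDown), rep(FALSE, nNull)),
        abs_change = 0.2)
    expect_equal(classifyEvolution(mk(2, 1))$category, "evolving")
    expect_equal(classifyEvolution(mk(1, 1))$category, "evolving")
    expect_equal(classifyEvolution(mk(3, 0))$category, "expanding")
    expect_equal(classifyEvolution(mk(1, 0))$category, "static")
    expect_equal(classifyEvolution(mk(0, 0))$category, "static")
    expect_equal(classifyEvolution(mk(0, 2))$category, "contracting")
    expect_equal(classifyEvolution(mk(0, 2),
        collapseContracting = TRUE)$category, "static")
    cl <- classifyEvolution(mk(2, 2, 6))
    expect_equal(cl$frac_changed, 0.4)
    expect_equal(cl$n_tested, 10L)
    # empty input warns and returns an untested static call
    expect_warning(cl0 <- classifyEvolution(
        S4Vectors::DataFrame(patient_id = character(),
            direction = character(), significant = logical(),
            abs_change = numeric())), "no drift results")
    expect_equal(cl0$category, "static")
    expect_equal(cl0$n_tested, 0L)
    # refuses mixed patients
    bad <- mk(1, 1)
    bad$patient_id <- c("P1", "P2", rep("P1", 5))
    expect_error(classifyEvolution(bad), "more than one patient")
})
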