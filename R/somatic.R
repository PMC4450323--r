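## Somatic calling and allele-frequency drift testing.
##
## The somatic caller compares allele counts across germline and the two
## tumor samples with a Monte-Carlo (permutation) chi-square test on the
## 2x3 allele-by-sample table; drift between the tumor time points is
## tested with the two-sided Fisher exact test on the 2x2 table, with
## Benjamini-Hochberg FDR control within each patient.

.localSeed <- function(seed) {
    if (is.null(seed)) return(invisible(NULL))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(seed)
        return(invisible(NULL))
    }
    old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    # restore the caller's RNG stream when the calling frame exits
    do.call(on.exit,
        list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
            add = TRUE),
        envir = parent.frame())
    invisible(NULL)
}

#' Permutation chi-square test for somatic variants
#'
#' Tests whether the alternate-allele fraction differs across the
#' germline sample and the two tumor samples by computing the Pearson
#' chi-square statistic of the 2x3 allele-by-sample count table and
#' comparing it with tables drawn under the pooled null with all margins
#' fixed (allele labels permuted across samples).  The Monte-Carlo
#' p-value uses the add-one correction \code{(1 + k) / (1 + nPerm)} where
#' \code{k} counts permuted statistics at least as large as the observed
#' one, so \code{p > 0} always.
#'
#' @param refCounts,altCounts Integer vectors of length 3 (germline, first
#'   tumor, second tumor) of reference/alternate read counts.
#' @param nPerm Number of permutations (default 10000).
#' @param seed Optional seed; the caller's RNG state is restored on exit.
#'
#' @return The Monte-Carlo p-value.
#' @seealso [callSomatic()] which applies the somatic thresholds.
#' @export
#' @examples
#' chi2PermutationTest(c(100, 70, 50), c(1, 30, 50), seed = 1)   # tiny p
#' chi2PermutationTest(c(50, 50, 50), c(0, 0, 0), seed = 1)      # p = 1
chi2PermutationTest <- function(refCounts, altCounts, nPerm = 10000,
    seed = NULL) {
    stopifnot(length(refCounts) == 3, length(altCounts) == 3)
    if (any(is.na(refCounts)) || any(is.na(altCounts)) ||
        any(refCounts < 0) || any(altCounts < 0))
        stop("read counts must be non-negative")
    depths <- refCounts + altCounts
    if (any(depths == 0))
        stop("zero depth in sample(s): ",
            paste(c("germline", "t1", "t2")[depths == 0], collapse = ", "))
    tab <- rbind(ref = refCounts, alt = altCounts)
    rs <- rowSums(tab)
    cs <- colSums(tab)
    if (any(rs == 0))  # all-ref (or all-alt) everywhere: no variation
        return(1)
    N <- sum(tab)
    E <- outer(rs, cs) / N
    obs <- sum((tab - E)^2 / E)
    .localSeed(seed)
    sim <- r2dtable(nPerm, rs, cs)
    m <- matrix(unlist(sim, use.names = FALSE), nrow = 6L)
    stats <- colSums((m - as.vector(E))^2 / as.vector(E))
    # count ties as extreme, as Monte-Carlo chi-square tests do
    (1 + sum(stats >= obs * (1 - 64 * .Machine$double.eps))) / (1 + nPerm)
}

#' Apply the somatic calling thresholds
#'
#' A site is called somatic when the permutation chi-square p-value is
#' below 0.001 and the germline alternate-allele fraction
#' \code{alt / (alt + ref)} is below 0.10 (which excludes germline
#' heterozygous and homozygous-alt sites).
#'
#' @param refCountG,altCountG Germline ref/alt read counts (vectorized).
#' @param pValue P-value(s) from [chi2PermutationTest()].
#' @param pThreshold,germlineAfThreshold The two thresholds.
#'
#' @return A [S4Vectors::DataFrame] with \code{p_value},
#'   \code{germline_af} and \code{is_somatic}.
#' @export
#' @examples
#' callSomatic(100, 1, 0.0005)$is_somatic   # TRUE
#' callSomatic(30, 30, 0.0005)$is_somatic   # FALSE: heterozygous germline
callSomatic <- function(refCountG, altCountG, pValue,
    pThreshold = 0.001, germlineAfThreshold = 0.10) {
    if (any(refCountG + altCountG == 0))
        stop("zero germline depth")
    af <- altCountG / (refCountG + altCountG)
    DataFrame(p_value = pValue, germline_af = af,
        is_somatic = pValue < pThreshold & af < germlineAfThreshold)
}

## Two-sided Fisher exact p for one 2x2 table [[ref1, alt1], [ref2, alt2]]:
## sum of hypergeometric probabilities not exceeding that of the observed
## table (with the usual 1e-7 relative tolerance for ties).
.fisher2x2 <- function(ref1, alt1, ref2, alt2) {
    m <- alt1 + alt2
    n <- ref1 + ref2
    k <- ref1 + alt1
    lo <- max(0L, k - n)
    hi <- min(k, m)
    support <- lo:hi
    d <- dhyper(support, m, n, k)
    min(1, sum(d[d <= dhyper(alt1, m, n, k) * (1 + 1e-7)]))
}

#' Fisher exact test for allele-frequency drift
#'
#' Two-sided Fisher exact test of the 2x2 table of ref/alt read counts at
#' one site in the two tumor samples, computed by direct summation of the
#' hypergeometric probabilities at most as likely as the observed table.
#' Agrees with \code{stats::fisher.test} to machine precision.
#'
#' @param ref1,alt1 Ref/alt counts at the first time point (vectorized).
#' @param ref2,alt2 Ref/alt counts at the second time point.
#'
#' @return Vector of two-sided p-values.
#' @export
#' @examples
#' fisherDriftTest(30, 70, 30, 70)   # identical proportions: p = 1
#' fisherDriftTest(10, 90, 40, 60)   # strong drift: p < 1e-4
fisherDriftTest <- function(ref1, alt1, ref2, alt2) {
    n <- length(ref1)
    stopifnot(length(alt1) == n, length(ref2) == n, length(alt2) == n)
    cnt <- cbind(ref1, alt1, ref2, alt2)
    if (any(is.na(cnt)) || any(cnt < 0))
        stop("read counts must be non-negative")
    if (any(ref1 + alt1 == 0) || any(ref2 + alt2 == 0))
        stop("both time points need depth > 0")
    vapply(seq_len(n), function(i)
        .fisher2x2(ref1[i], alt1[i], ref2[i], alt2[i]), numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment: with sorted p-values, \code{q_(i) = min
#' over j >= i of p_(j) * n / j}, returned in the input order.  This is
#' \code{stats::p.adjust(method = "BH")} with input validation.
#'
#' @param p Numeric vector of p-values in \code{[0,1]}.
#' @return Vector of q-values.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhFDR <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0,1]")
    p.adjust(p, method = "BH")
}

#' Per-site allele-frequency drift testing for a cohort
#'
#' Runs [fisherDriftTest()] on the two tumor samples of every site in a
#' [TriSampleCounts()] table and applies [bhFDR()] within each patient
#' (the FDR scope that feeds the per-patient evolution classification).
#' Direction compares the point estimates of the allele fractions; exact
#' ties are excluded from both directions.
#'
#' @param counts A \code{TriSampleCounts} object (typically the
#'   deep-targeted validation counts at somatic sites).
#' @param fdr Significance threshold on the q-value (default 0.05).
#'
#' @return A [S4Vectors::DataFrame] with one row per site:
#'   \code{site_id}, \code{patient_id}, \code{af_t1}, \code{af_t2},
#'   \code{fisher_p}, \code{q_value}, \code{direction} (\code{"up"},
#'   \code{"down"} or \code{NA} for ties), \code{abs_change} and
#'   \code{significant}.
#' @export
#' @examples
#' tsc <- TriSampleCounts(data.frame(site_id = c("s1", "s2"),
#'     patient_id = "P1", chrom = "chr1", pos = c(1, 2),
#'     ref_count_g = 800, alt_count_g = 0,
#'     ref_count_t1 = c(600, 600), alt_count_t1 = c(200, 200),
#'     ref_count_t2 = c(400, 590), alt_count_t2 = c(400, 210)))
#' driftTest(tsc)
driftTest <- function(counts, fdr = 0.05) {
    stopifnot(is(counts, "TriSampleCounts"))
    af1 <- counts$alt_count_t1 / (counts$ref_count_t1 + counts$alt_count_t1)
    af2 <- counts$alt_count_t2 / (counts$ref_count_t2 + counts$alt_count_t2)
    p <- fisherDriftTest(counts$ref_count_t1, counts$alt_count_t1,
        counts$ref_count_t2, counts$alt_count_t2)
    q <- rep(NA_real_, length(p))
    for (pid in unique(counts$patient_id)) {
        i <- counts$patient_id == pid
        q[i] <- bhFDR(p[i])
    }
    dir <- ifelse(af2 > af1, "up", ifelse(af2 < af1, "down", NA_character_))
    DataFrame(site_id = counts$site_id, patient_id = counts$patient_id,
        af_t1 = af1, af_t2 = af2, fisher_p = p, q_value = q,
        direction = dir, abs_change = abs(af2 - af1),
        significant = q < fdr)
}

#' Classify a leukemia's pattern of subclonal change
#'
#' From the drift results of one patient, counts significantly rising and
#' falling variants and assigns the somatic-evolution category:
#' \describe{
#'   \item{evolving}{at least one variant rose and at least one fell;}
#'   \item{expanding}{two or more rose and none fell;}
#'   \item{static}{no or only one variant changed;}
#'   \item{contracting}{two or more fell and none rose.  This quadrant is
#'     not covered by the three-category scheme; it is labelled
#'     explicitly, with \code{collapseContracting = TRUE} folding it into
#'     \code{"static"}.}
#' }
#' Also reports the median absolute allele-frequency change among
#' significant sites and the fraction of tested sites that changed.
#'
#' @param drift Drift results for one patient, as returned by
#'   [driftTest()] (rows from other patients are rejected).
#' @param patientId Optional patient id (taken from \code{drift} if
#'   absent).
#' @param collapseContracting Fold the contracting quadrant into static?
#'
#' @return A [S4Vectors::DataFrame] with one row: \code{patient_id},
#'   \code{n_up}, \code{n_down}, \code{n_tested}, \code{category},
#'   \code{median_abs_change_significant}, \code{frac_changed}.
#' @export
#' @examples
#' d <- S4Vectors::DataFrame(patient_id = "P1",
#'     direction = c("up", "up", "down"), significant = TRUE,
#'     abs_change = c(0.1, 0.2, 0.15))
#' classifyEvolution(d)$category  # evolving
classifyEvolution <- function(drift, patientId = NULL,
    collapseContracting = FALSE) {
    if (nrow(drift) == 0) {
        warning("no drift results supplied; returning 'static' with ",
            "n_tested = 0")
        return(DataFrame(patient_id = patientId %||% NA_character_,
            n_up = 0L, n_down = 0L, n_tested = 0L, category = "static",
            median_abs_change_significant = NA_real_,
            frac_changed = NA_real_))
    }
    pid <- unique(drift$patient_id)
    if (length(pid) > 1)
        stop("drift results from more than one patient: ",
            paste(pid, collapse = ", "))
    if (is.null(patientId)) patientId <- pid
    sig <- !is.na(drift$significant) & drift$significant &
        !is.na(drift$direction)
    nUp <- sum(sig & drift$direction == "up")
    nDown <- sum(sig & drift$direction == "down")
    category <- if (nUp >= 1 && nDown >= 1) "evolving"
        else if (nUp >= 2 && nDown == 0) "expanding"
        else if (nUp + nDown <= 1) "static"
        else "contracting"
    if (collapseContracting && category == "contracting")
        category <- "static"
    DataFrame(patient_id = patientId, n_up = nUp, n_down = nDown,
        n_tested = nrow(drift), category = category,
        median_abs_change_significant =
            if (any(sig)) median(drift$abs_change[sig]) else NA_real_,
        frac_changed = (nUp + nDown) / nrow(drift))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
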