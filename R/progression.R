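## Discovery of progression-associated CpGs: per-CpG paired Wilcoxon
## signed-rank tests across patients, BH-FDR, and the summary scores
## derived from the per-patient beta changes.

.pairedDeltas <- function(betas) {
    cd <- as.data.frame(colData(betas))
    if (any(is.na(cd$timepoint)))
        stop("all samples need a 't1'/'t2' timepoint for pairing")
    pats <- unique(cd$patient_id)
    t1 <- t2 <- character(length(pats))
    for (i in seq_along(pats)) {
        s1 <- rownames(cd)[cd$patient_id == pats[i] & cd$timepoint == "t1"]
        s2 <- rownames(cd)[cd$patient_id == pats[i] & cd$timepoint == "t2"]
        if (length(s1) != 1 || length(s2) != 1)
            stop("patient ", pats[i], " must contribute exactly one t1 ",
                "and one t2 sample")
        t1[i] <- s1
        t2[i] <- s2
    }
    b <- betaValues(betas)
    b[, t2, drop = FALSE] - b[, t1, drop = FALSE]
}

#' Paired Wilcoxon test for progression-associated CpGs
#'
#' For every CpG, pairs each patient's first and second time point and
#' applies the two-sided Wilcoxon signed-rank test to the paired beta
#' values across patients.  Zero differences are dropped (signed-rank
#' convention); the exact null distribution is used for n <= 25 untied
#' differences and the normal approximation with continuity correction
#' otherwise.  Q-values come from [bhFDR()] across CpGs; a CpG is
#' significant at \code{q < fdr}, with direction given by the sign of the
#' median paired delta.
#'
#' @param betas A [BetaMatrix()] with one t1 and one t2 column per
#'   patient (composition-adjusted values, typically).
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @param minPairs Minimum number of complete pairs required (default 6).
#'
#' @return A [S4Vectors::DataFrame] with one row per CpG:
#'   \code{cpg_id}, \code{median_paired_delta}, \code{wilcoxon_p},
#'   \code{q_value}, \code{direction}, \code{significant},
#'   \code{untested} (all differences zero).
#' @export
pairedProgressionTest <- function(betas, fdr = 0.05, minPairs = 6) {
    D <- .pairedDeltas(betas)
    if (ncol(D) < minPairs)
        stop("need at least ", minPairs, " complete patient pairs, got ",
            ncol(D))
    n <- ncol(D)
    p <- apply(D, 1, function(d) {
        d <- d[!is.na(d)]
        nz <- d[d != 0]
        if (length(nz) == 0) return(1)
        useExact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
        suppressWarnings(wilcox.test(nz, exact = useExact,
            correct = TRUE)$p.value)
    })
    p <- unname(p)
    untested <- unname(apply(D, 1, function(d) all(d == 0, na.rm = TRUE)))
    med <- unname(apply(D, 1, median, na.rm = TRUE))
    q <- bhFDR(p)
    DataFrame(cpg_id = rownames(D), median_paired_delta = med,
        wilcoxon_p = p, q_value = q,
        direction = ifelse(med > 0, "up", ifelse(med < 0, "down",
            NA_character_)),
        significant = q < fdr & !untested, untested = untested)
}

#' Cumulative methylation deviation during progression
#'
#' Sum of absolute beta changes over the progression-associated CpGs --
#' the per-patient "methylation score change" that summarizes how much a
#' leukemia's methylome moved between the two time points.
#'
#' @param betasT1,betasT2 Named beta vectors of one patient's samples.
#' @param progressionCpgs CpG ids over which to accumulate.
#'
#' @return The score (0 for identical vectors; empty set gives 0 with a
#'   warning).
#' @export
#' @examples
#' progressionScore(c(a = 0.5, b = 0.5), c(a = 0.6, b = 0.4), c("a", "b"))
progressionScore <- function(betasT1, betasT2, progressionCpgs) {
    if (length(progressionCpgs) == 0) {
        warning("empty progression CpG set; score is 0")
        return(0)
    }
    missing <- setdiff(progressionCpgs, intersect(names(betasT1),
        names(betasT2)))
    if (length(missing))
        stop("sites absent from the beta vectors: ",
            paste(head(missing, 5), collapse = ", "))
    sum(abs(betasT2[progressionCpgs] - betasT1[progressionCpgs]))
}

#' Count per-patient methylation changes above magnitude thresholds
#'
#' For each patient, counts CpGs whose absolute beta change exceeds each
#' threshold (defaults 5% and 20%), plus cohort means -- the "sites
#' changing more than 5%/20% per patient" bookkeeping.
#'
#' @param deltas Numeric matrix of per-CpG beta changes, CpGs x patients.
#' @param thresholds Numeric vector of magnitude cutoffs.
#'
#' @return A list with \code{per_patient} (patients x thresholds count
#'   matrix) and \code{cohort_mean} (mean count per threshold).
#' @export
#' @examples
#' d <- cbind(P1 = c(0.25, 0.10, 0.01), P2 = c(0.06, -0.06, 0))
#' changeMagnitudeSummary(d)
changeMagnitudeSummary <- function(deltas, thresholds = c(0.05, 0.20)) {
    deltas <- as.matrix(deltas)
    counts <- vapply(thresholds, function(th)
        colSums(abs(deltas) > th, na.rm = TRUE),
        numeric(ncol(deltas)))
    counts <- matrix(counts, nrow = ncol(deltas),
        dimnames = list(colnames(deltas), paste0("gt_", thresholds)))
    list(per_patient = counts, cohort_mean = colMeans(counts))
}

#' Enrichment of a CpG set among the most-changing sites
#'
#' Flags the CpGs in the top and bottom \code{q} quantiles of the mean
#' beta change (for example across sorted-cell samples), builds the 2x2
#' table of quantile flag versus set membership, and reports the odds
#' ratio \code{(a*d)/(b*c)} with a two-sided Fisher exact p-value.  Used
#' to ask whether progression-associated CpGs (or H3K27me3-flagged ones)
#' are over-represented among the largest sorted-cell changes.
#'
#' @param meanDeltas Named numeric vector of mean beta changes per CpG.
#' @param cpgSet CpG ids of the set tested for enrichment.
#' @param q Quantile in \code{(0, 0.5]} (default 0.05: top and bottom 5%).
#' @param tail \code{"both"} (default), \code{"top"} or \code{"bottom"}.
#'
#' @return A list with the 2x2 \code{table}, \code{odds_ratio} (NA when a
#'   margin is degenerate) and \code{p_value}.
#' @export
quantileChangeEnrichment <- function(meanDeltas, cpgSet, q = 0.05,
    tail = c("both", "top", "bottom")) {
    tail <- match.arg(tail)
    if (q <= 0 || q > 0.5)
        stop("q must lie in (0, 0.5]")
    lo <- quantile(meanDeltas, q, na.rm = TRUE)
    hi <- quantile(meanDeltas, 1 - q, na.rm = TRUE)
    flagged <- switch(tail,
        both = meanDeltas <= lo | meanDeltas >= hi,
        top = meanDeltas >= hi,
        bottom = meanDeltas <= lo)
    inSet <- names(meanDeltas) %in% cpgSet
    a <- sum(flagged & inSet)
    b <- sum(flagged & !inSet)
    cc <- sum(!flagged & inSet)
    d <- sum(!flagged & !inSet)
    tab <- matrix(c(a, cc, b, d), 2,
        dimnames = list(c("flagged", "not_flagged"),
            c("in_set", "not_in_set")))
    orv <- if (b == 0 || cc == 0) {
        if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * cc)
    list(table = tab, odds_ratio = orv,
        p_value = fisher.test(matrix(c(a, b, cc, d), 2))$p.value)
}

#' Direction summary of significant progression CpGs
#'
#' Among significant CpGs, the number and percentage whose methylation
#' increased -- the "fraction of significant sites showing increases"
#' bookkeeping.
#'
#' @param results Output of [pairedProgressionTest()] (or any table with
#'   \code{significant} and \code{direction} columns).
#'
#' @return A list with \code{n_significant}, \code{n_up} and
#'   \code{pct_increasing}.
#' @export
directionSummary <- function(results) {
    sig <- !is.na(results$significant) & results$significant
    nUp <- sum(sig & results$direction == "up", na.rm = TRUE)
    list(n_significant = sum(sig), n_up = nUp,
        pct_increasing = 100 * nUp / sum(sig))
}
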