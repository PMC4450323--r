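## Cohort bookkeeping.  Every fraction in a report is recomputed from the
## per-unit tables it summarizes; nothing is stored independently.

#' Validation bookkeeping for somatic variant calls
#'
#' From a per-site table flagging which called sSNVs were interrogated by
#' targeted validation sequencing and which of those validated, computes
#' the interrogated and validated percentages.
#'
#' @param sites A \code{data.frame}/\code{DataFrame} with one row per
#'   called sSNV and logical columns \code{interrogated} and
#'   \code{validated} (\code{validated} implies \code{interrogated}).
#'
#' @return A list with \code{n_called}, \code{n_interrogated},
#'   \code{n_validated}, \code{pct_interrogated} (of called) and
#'   \code{pct_validated} (of interrogated).
#' @export
#' @examples
#' s <- data.frame(interrogated = c(TRUE, TRUE, FALSE),
#'     validated = c(TRUE, FALSE, FALSE))
#' validationSummary(s)
validationSummary <- function(sites) {
    sites <- as.data.frame(sites)
    if (any(sites$validated & !sites$interrogated))
        stop("a site cannot validate without being interrogated")
    nC <- nrow(sites)
    nI <- sum(sites$interrogated)
    nV <- sum(sites$validated)
    list(n_called = nC, n_interrogated = nI, n_validated = nV,
        pct_interrogated = 100 * nI / nC,
        pct_validated = 100 * nV / nI)
}

#' Drift bookkeeping across validated sites
#'
#' From per-site drift results, the percentage of sites changing
#' significantly and, among those, the percentage with an absolute
#' allele-frequency change above a threshold (default 10%).
#'
#' @param drift Output of [driftTest()] (or any table with
#'   \code{significant} and \code{abs_change} columns).
#' @param largeChange Threshold on \code{abs_change} (default 0.10).
#'
#' @return A list with \code{n_tested}, \code{n_significant},
#'   \code{n_large}, \code{pct_significant},
#'   \code{pct_large_among_significant}.
#' @export
driftSummary <- function(drift, largeChange = 0.10) {
    sig <- !is.na(drift$significant) & drift$significant
    nLarge <- sum(sig & drift$abs_change > largeChange)
    list(n_tested = nrow(drift), n_significant = sum(sig),
        n_large = nLarge,
        pct_significant = 100 * sum(sig) / nrow(drift),
        pct_large_among_significant = 100 * nLarge / sum(sig))
}

#' Category bookkeeping across patients
#'
#' Percentages of patients in each somatic-evolution category, from the
#' per-patient calls.
#'
#' @param calls Row-bound output of [classifyEvolution()] over the
#'   cohort.
#'
#' @return A list with \code{n_patients}, \code{counts} (named) and
#'   \code{pct} (named percentages).
#' @export
categorySummary <- function(calls) {
    n <- nrow(calls)
    counts <- table(factor(calls$category,
        levels = c("evolving", "expanding", "static", "contracting")))
    list(n_patients = n, counts = c(counts),
        pct = 100 * c(counts) / n)
}

#' Assemble a cohort report
#'
#' Combines the per-unit tables of a full run into one report whose
#' summary fractions are all recomputed from those tables.
#'
#' @param evolutionCalls Per-patient calls ([classifyEvolution()]).
#' @param drift Per-site drift results ([driftTest()]).
#' @param validation Optional per-site validation flags
#'   (see [validationSummary()]).
#' @param progression Optional per-CpG results
#'   ([pairedProgressionTest()]).
#' @param cnaGroups Optional grouped sCNAs ([groupCNASegments()]).
#'
#' @return A list of the component summaries plus the input tables.
#' @export
cohortReport <- function(evolutionCalls, drift, validation = NULL,
    progression = NULL, cnaGroups = NULL) {
    rep <- list(
        category = categorySummary(evolutionCalls),
        drift = driftSummary(drift),
        evolution_calls = evolutionCalls,
        drift_results = drift)
    if (!is.null(validation))
        rep$validation <- validationSummary(validation)
    if (!is.null(progression)) {
        rep$direction <- directionSummary(progression)
        rep$progression_results <- progression
    }
    if (!is.null(cnaGroups))
        rep$cna <- recurrentLocusSummary(cnaGroups,
            nPatients = nrow(evolutionCalls))
    rep
}

#' Render a cohort report as text
#'
#' @param report Output of [cohortReport()].
#' @return A character vector of lines (also usable with
#'   \code{writeLines}).
#' @export
formatCohortReport <- function(report) {
    ln <- c("Cohort report", "=============")
    cs <- report$category
    ln <- c(ln, sprintf("Patients: %d", cs$n_patients),
        sprintf("  %-12s %3d (%.0f%%)", names(cs$counts), cs$counts,
            cs$pct))
    ds <- report$drift
    ln <- c(ln, sprintf(
        "Drift: %d/%d sites significant (%.0f%%), %d/%d >10%% (%.0f%%)",
        ds$n_significant, ds$n_tested, ds$pct_significant, ds$n_large,
        ds$n_significant, ds$pct_large_among_significant))
    if (!is.null(report$validation)) {
        vs <- report$validation
        ln <- c(ln, sprintf(
            "Validation: %d/%d interrogated (%.0f%%), %d/%d validated (%.0f%%)",
            vs$n_interrogated, vs$n_called, vs$pct_interrogated,
            vs$n_validated, vs$n_interrogated, vs$pct_validated))
    }
    if (!is.null(report$direction)) {
        dr <- report$direction
        ln <- c(ln, sprintf(
            "Methylation: %d significant CpGs, %d increasing (%.0f%%)",
            dr$n_significant, dr$n_up, dr$pct_increasing))
    }
    if (!is.null(report$cna)) {
        cn <- report$cna
        ln <- c(ln, sprintf(
            "sCNA: %d/%d patients with a recurrent-locus alteration (%.0f%%)",
            cn$n_patients_recurrent, cn$n_patients, cn$pct_recurrent))
    }
    ln
}
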