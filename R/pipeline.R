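## End-to-end orchestration.  A run configuration (YAML or list) names
## the inputs and thresholds; runGenetic/runMethylation/runAll read the
## inputs, execute the corresponding analysis and write every
## intermediate table plus a human-readable summary into the output
## directory.  Runs are deterministic given the configured seed, which
## is echoed (with the whole configuration) into the outputs.

.defaultConfig <- function() list(
    somatic_p = 0.001, germline_af = 0.10, fdr = 0.05,
    window = 200L, diff = 0.10, quantile = 0.05,
    magnitude = c(0.05, 0.20), merge_distance = 1e6,
    n_perm = 10000L, n_resamples = 1000L, seed = 1L,
    adjust_composition = TRUE, collapse_contracting = FALSE,
    out_dir = "progressionkit_out")

#' Load a run configuration
#'
#' Reads a YAML file of paths and thresholds and merges it over the
#' defaults (somatic p 0.001, germline allele fraction 0.10, FDR 0.05,
#' 200 bp windows, 10% difference calls, 5% quantiles, magnitude
#' thresholds 5%/20%, 1 Mb merge distance, 10000 permutations, 1000
#' resamples).  Every unknown key is kept, so input paths live in the
#' same file.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @param overrides Named list applied after the file (CLI flags).
#'
#' @return A named list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- .defaultConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        cfg[names(user)] <- user
    }
    cfg[names(overrides)] <- overrides
    err <- character()
    for (k in c("somatic_p", "germline_af", "fdr", "diff", "quantile"))
        if (cfg[[k]] <= 0 || cfg[[k]] > 1)
            err <- c(err, paste0(k, " must lie in (0, 1]"))
    if (cfg$window <= 0 || cfg$window %% 2 != 0)
        err <- c(err, "window must be positive and even")
    if (length(err)) stop(paste(err, collapse = "; "))
    cfg
}

.prepOut <- function(config) {
    dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(config[["out_dir"]], "config.yaml"))
    logLine <- function(...) {
        msg <- paste0(...)
        message(msg)
        cat(msg, "\n", file = file.path(config[["out_dir"]], "run.log"),
            append = TRUE)
    }
    logLine("ProgressionKit ",
        as.character(utils::packageVersion("ProgressionKit")),
        " seed=", config[["seed"]])
    logLine
}

#' Run the genetic arm of the pipeline
#'
#' Somatic calling on the exome-depth counts (permutation chi-square at
#' p < \code{somatic_p} with germline allele fraction <
#' \code{germline_af}), drift testing of the somatic sites on the
#' amplicon-depth counts (Fisher exact, BH-FDR within patient),
#' per-patient evolution classification, and sCNA grouping when segment
#' calls are supplied.  All tables are written as TSV under
#' \code{config[["out_dir"]]}.
#'
#' @param config A configuration list (see [readRunConfig()]) with
#'   \code{exome_counts} and \code{amplicon_counts} paths (TSV, see
#'   [readAlleleCounts()]) and optionally \code{cna_segments}.
#'   Alternatively pass loaded objects via \code{exome}/\code{amplicon}/
#'   \code{segments} elements.
#'
#' @return A [cohortReport()] list, invisibly writing
#'   \code{somatic_calls.tsv}, \code{drift_results.tsv},
#'   \code{evolution_calls.tsv}, \code{cna_groups.tsv} and
#'   \code{summary.txt}.
#' @export
runGenetic <- function(config) {
    logLine <- .prepOut(config)
    exome <- config[["exome"]] %||%
        readAlleleCounts(config[["exome_counts"]])
    amplicon <- config[["amplicon"]] %||%
        readAlleleCounts(config[["amplicon_counts"]])
    logLine("genetic arm: ", nrow(exome), " sites, ",
        length(unique(exome$patient_id)), " patients")
    p <- vapply(seq_len(nrow(exome)), function(i)
        chi2PermutationTest(
            c(exome$ref_count_g[i], exome$ref_count_t1[i],
                exome$ref_count_t2[i]),
            c(exome$alt_count_g[i], exome$alt_count_t1[i],
                exome$alt_count_t2[i]),
            nPerm = config[["n_perm"]],
            seed = config[["seed"]] + i),
        numeric(1))
    calls <- callSomatic(exome$ref_count_g, exome$alt_count_g, p,
        pThreshold = config[["somatic_p"]],
        germlineAfThreshold = config[["germline_af"]])
    somatic <- cbind(DataFrame(site_id = exome$site_id,
        patient_id = exome$patient_id), calls)
    .writeTSV(somatic, file.path(config[["out_dir"]], "somatic_calls.tsv"))
    keep <- amplicon$site_id %in%
        somatic$site_id[somatic$is_somatic]
    drift <- driftTest(amplicon[keep, ], fdr = config[["fdr"]])
    .writeTSV(drift, file.path(config[["out_dir"]], "drift_results.tsv"))
    calls <- do.call(rbind, lapply(unique(drift$patient_id),
        function(pid) classifyEvolution(
            drift[drift$patient_id == pid, , drop = FALSE],
            collapseContracting = isTRUE(config[["collapse_contracting"]]))))
    .writeTSV(calls, file.path(config[["out_dir"]], "evolution_calls.tsv"))
    groups <- NULL
    segs <- config[["segments"]] %||% (if (!is.null(config[["cna_segments"]]))
        readCNASegments(config[["cna_segments"]]))
    if (!is.null(segs)) {
        groups <- groupCNASegments(segs,
            mergeDistance = config[["merge_distance"]])
        .writeTSV(groups, file.path(config[["out_dir"]], "cna_groups.tsv"))
    }
    report <- cohortReport(calls, drift, cnaGroups = groups)
    writeLines(formatCohortReport(report),
        file.path(config[["out_dir"]], "summary.txt"))
    logLine("genetic arm done: ",
        paste(names(report$category$counts),
            report$category$counts, collapse = ", "))
    report
}

#' Run the methylation arm of the pipeline
#'
#' Deconvolution of every sample against the reference panel,
#' composition adjustment (unless \code{adjust_composition} is FALSE),
#' paired Wilcoxon progression testing at BH-FDR < \code{fdr}, magnitude
#' summaries, and -- when a manifest and peaks are supplied -- window
#' overlap flags with hypergeometric enrichment.
#'
#' @param config A configuration list with \code{beta_matrix} +
#'   \code{beta_metadata} and \code{reference_panel} paths (or loaded
#'   \code{beta}/\code{panel} objects), optionally \code{manifest} /
#'   \code{annotation} and \code{peaks_bed} / \code{peaks}.
#'
#' @return A list with \code{composition}, \code{adjusted},
#'   \code{progression}, \code{magnitude}, and (when annotated)
#'   \code{h3k27me3_flags} and \code{peak_enrichment}; tables are
#'   written under \code{config[["out_dir"]]}.
#' @export
runMethylation <- function(config) {
    logLine <- .prepOut(config)
    beta <- config[["beta"]] %||%
        readBetaMatrix(config[["beta_matrix"]], config[["beta_metadata"]])
    panel <- config[["panel"]] %||%
        readReferencePanel(config[["reference_panel"]])
    logLine("methylation arm: ", nrow(beta), " CpGs, ", ncol(beta),
        " samples")
    comp <- deconvolve(beta, panel)
    .writeTSV(data.frame(sample_id = rownames(proportions(comp)),
        proportions(comp)),
        file.path(config[["out_dir"]], "composition.tsv"))
    adjusted <- if (isTRUE(config[["adjust_composition"]]))
        adjustForComposition(beta, comp) else beta
    writeBetaMatrix(adjusted,
        file.path(config[["out_dir"]], "adjusted_beta.tsv"),
        file.path(config[["out_dir"]], "adjusted_beta_meta.tsv"))
    prog <- pairedProgressionTest(adjusted, fdr = config[["fdr"]])
    .writeTSV(prog, file.path(config[["out_dir"]], "progression_results.tsv"))
    deltas <- .pairedDeltas(adjusted)
    mag <- changeMagnitudeSummary(deltas,
        thresholds = config[["magnitude"]])
    .writeTSV(data.frame(patient_id = rownames(mag$per_patient),
        mag$per_patient),
        file.path(config[["out_dir"]], "magnitude_counts.tsv"))
    out <- list(composition = comp, adjusted = adjusted,
        progression = prog, magnitude = mag,
        direction = directionSummary(prog))
    ann <- config[["annotation"]] %||% (if (!is.null(config[["manifest"]]))
        readManifest(config[["manifest"]]))
    peaks <- config[["peaks"]] %||% (if (!is.null(config[["peaks_bed"]]))
        readPeakBed(config[["peaks_bed"]]))
    if (!is.null(ann) && !is.null(peaks)) {
        flags <- windowPeakOverlap(ann, peaks, window = config[["window"]])
        sig <- prog$cpg_id[prog$significant]
        sigIn <- intersect(sig, ann$cpg_id)
        enr <- hypergeometricEnrichment(
            nUniverse = nrow(ann),
            nFlaggedUniverse = sum(flags),
            nSelected = length(sigIn),
            nFlaggedSelected = sum(flags[sigIn]))
        out$h3k27me3_flags <- flags
        out$peak_enrichment <- enr
        .writeTSV(data.frame(cpg_id = names(flags),
            near_peak = unname(flags)),
            file.path(config[["out_dir"]], "peak_flags.tsv"))
    }
    summary <- c(sprintf("Significant CpGs: %d (%d increasing, %.0f%%)",
        out$direction$n_significant, out$direction$n_up,
        out$direction$pct_increasing),
        sprintf("Mean sites changing > %s: %s",
            paste(config[["magnitude"]], collapse = "/"),
            paste(round(mag$cohort_mean, 1), collapse = "/")))
    writeLines(summary, file.path(config[["out_dir"]],
        "methylation_summary.txt"))
    logLine(summary[1])
    out
}

#' Run both arms of the pipeline
#'
#' @param config A configuration list naming the inputs of both
#'   [runGenetic()] and [runMethylation()].
#' @return A list with \code{genetic} and \code{methylation} reports.
#' @export
runAll <- function(config) {
    list(genetic = runGenetic(config),
        methylation = runMethylation(config))
}
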