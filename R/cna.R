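## Grouping of somatic copy-number segments.  Segment calls that are near
## each other on the same chromosome -- including the same event called at
## both time points -- are merged into one sCNA group and counted as a
## single variant per patient.

#' Group somatic copy-number segments into per-patient sCNA units
#'
#' Single-linkage merge of same-chromosome segments whose gap is at most
#' \code{mergeDistance}, across both time points, within each patient.
#' Each resulting group is counted as one variant; its \code{presence}
#' records whether member segments were seen at both time points or only
#' one, and \code{locus_label} names the recurrent CLL locus the group
#' overlaps (11q, 12, 13q, 17p) or \code{"other"}.
#'
#' @param segments A \code{data.frame}/\code{DataFrame} of segment calls
#'   with columns \code{patient_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{timepoint} (\code{"t1"} or
#'   \code{"t2"}) and optionally \code{copy_number}, \code{confidence}.
#' @param mergeDistance Maximum gap in bp between merged segments
#'   (default 1e6; segmentation jitter is merged, focal events 2 Mb apart
#'   are kept separate).
#' @param loci Optional \code{data.frame} of recurrent loci with columns
#'   \code{label}, \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open); defaults to the bundled CLL table, see [cllRecurrentLoci()].
#'
#' @return A [S4Vectors::DataFrame] with one row per group:
#'   \code{patient_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{n_segments}, \code{presence} (\code{"both"},
#'   \code{"first_only"}, \code{"second_only"}) and \code{locus_label}.
#' @export
#' @examples
#' seg <- data.frame(patient_id = "P1", chrom = "chr13",
#'     start = c(49e6, 49.1e6), end = c(50e6, 50.2e6),
#'     timepoint = c("t1", "t2"))
#' groupCNASegments(seg)   # one group, presence "both", locus 13q
groupCNASegments <- function(segments, mergeDistance = 1e6,
    loci = cllRecurrentLoci()) {
    segments <- as.data.frame(segments)
    need <- c("patient_id", "chrom", "start", "end", "timepoint")
    missing <- setdiff(need, colnames(segments))
    if (length(missing))
        stop("segment table lacks columns: ",
            paste(missing, collapse = ", "))
    if (any(segments$end <= segments$start))
        stop("segments must satisfy start < end (0-based half-open)")
    lociGR <- GRanges(loci$chrom,
        IRanges(loci$start + 1L, loci$end))
    out <- lapply(split(segments, segments$patient_id), function(s) {
        gr <- GRanges(s$chrom, IRanges(s$start + 1L, s$end))
        merged <- reduce(gr, min.gapwidth = mergeDistance + 1)
        hit <- findOverlaps(gr, merged)
        grpOf <- integer(length(gr))
        grpOf[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
        tp <- split(s$timepoint, grpOf)
        presence <- vapply(seq_along(merged), function(g) {
            t <- unique(tp[[as.character(g)]])
            if (all(c("t1", "t2") %in% t)) "both"
            else if (identical(t, "t1")) "first_only" else "second_only"
        }, character(1))
        # loci and segments legitimately cover different chromosomes
        lhit <- suppressWarnings(
            findOverlaps(merged, lociGR, select = "first"))
        DataFrame(patient_id = s$patient_id[1],
            chrom = as.character(seqnames(merged)),
            start = start(merged) - 1L, end = end(merged),
            n_segments = as.integer(table(factor(grpOf,
                levels = seq_along(merged)))),
            presence = presence,
            locus_label = ifelse(is.na(lhit), "other",
                loci$label[lhit]))
    })
    res <- do.call(rbind, unname(out))
    rownames(res) <- NULL
    res
}

#' Recurrently altered CLL loci
#'
#' Loads the bundled coordinate table of the four copy-number loci
#' recurrently altered in CLL (del(11q), trisomy 12, del(13q14),
#' del(17p)), as approximate hg19 intervals.  The table is configuration:
#' supply your own via the \code{loci} argument of
#' [groupCNASegments()] to change it.
#'
#' @param path Optional path to an alternative TSV with columns
#'   \code{label}, \code{chrom}, \code{start}, \code{end}.
#' @return A \code{data.frame}.
#' @export
#' @examples
#' cllRecurrentLoci()
cllRecurrentLoci <- function(path = system.file("extdata",
    "cll_recurrent_loci.tsv", package = "ProgressionKit")) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Summarize recurrent-locus sCNA burden across patients
#'
#' Counts, over a cohort of grouped sCNAs, the patients carrying at least
#' one group at a recurrent CLL locus.
#'
#' @param groups Output of [groupCNASegments()] over the whole cohort.
#' @param nPatients Total number of patients assayed (patients without
#'   any sCNA contribute to the denominator).
#'
#' @return A list with \code{n_patients_recurrent}, \code{n_patients} and
#'   \code{pct_recurrent}.
#' @export
recurrentLocusSummary <- function(groups, nPatients) {
    hit <- unique(groups$patient_id[groups$locus_label != "other"])
    if (length(hit) > nPatients)
        stop("more patients with recurrent loci than patients assayed")
    list(n_patients_recurrent = length(hit), n_patients = nPatients,
        pct_recurrent = 100 * length(hit) / nPatients)
}
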