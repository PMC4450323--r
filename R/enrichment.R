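## Annotation of significant CpGs: window overlap with ChIP-seq peaks,
## hypergeometric enrichment, probe-bias-corrected gene-set tests and
## fixed-list overlap tests.

#' Flag CpGs whose window overlaps ChIP-seq peaks
#'
#' Centers a window (default 200 bp) on each probe coordinate and flags
#' the CpG when that window intersects at least one peak by at least
#' 1 bp.  Probe positions are 1-based single-bp coordinates; the window
#' is the 0-based half-open interval
#' \code{[pos - window/2, pos + window/2)}.  Chromosomes present among
#' probes but absent from the peak set produce a warning and no overlap.
#'
#' @param cpgs A \code{data.frame}/\code{DataFrame} with columns
#'   \code{cpg_id}, \code{chrom}, \code{pos} (1-based).
#' @param peaks A [GenomicRanges::GRanges] of peaks (e.g. from
#'   [readPeakBed()]), or a BED-like data.frame with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param window Window width in bp; must be even (default 200).
#'
#' @return A logical vector along \code{cpgs} rows, named by
#'   \code{cpg_id}.
#' @export
#' @examples
#' cpgs <- data.frame(cpg_id = c("a", "b"), chrom = "chr1",
#'     pos = c(1000, 1000))
#' peaks <- data.frame(chrom = "chr1", start = c(1099, 5000),
#'     end = c(1200, 5100))
#' windowPeakOverlap(cpgs, peaks)   # a is flagged: window reaches 1099
windowPeakOverlap <- function(cpgs, peaks, window = 200) {
    if (window <= 0 || window %% 2 != 0)
        stop("window must be a positive even number of bp")
    cpgs <- as.data.frame(cpgs)
    if (!is(peaks, "GRanges")) {
        peaks <- as.data.frame(peaks)
        peaks <- GRanges(peaks$chrom,
            IRanges(peaks$start + 1L, peaks$end))
    }
    missingChrom <- setdiff(unique(cpgs$chrom),
        unique(as.character(seqnames(peaks))))
    if (length(missingChrom))
        warning("chromosomes without peaks: ",
            paste(missingChrom, collapse = ", "),
            " (treated as no overlap)")
    half <- window / 2
    win <- GRanges(cpgs$chrom,
        IRanges(start = cpgs$pos - half + 1L, end = cpgs$pos + half))
    flagged <- suppressWarnings(
        IRanges::overlapsAny(win, peaks, minoverlap = 1L))
    setNames(flagged, cpgs$cpg_id)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least \code{nFlaggedSelected} flagged
#' items in a selection of size \code{nSelected} drawn without
#' replacement from a universe of \code{nUniverse} items of which
#' \code{nFlaggedUniverse} are flagged.
#'
#' @param nUniverse,nFlaggedUniverse,nSelected,nFlaggedSelected The four
#'   counts.
#'
#' @return The upper-tail p-value \code{P(X >= nFlaggedSelected)}.
#' @export
#' @examples
#' hypergeometricEnrichment(100, 20, 10, 8)
hypergeometricEnrichment <- function(nUniverse, nFlaggedUniverse,
    nSelected, nFlaggedSelected) {
    if (nFlaggedUniverse > nUniverse || nSelected > nUniverse ||
        nFlaggedSelected > min(nSelected, nFlaggedUniverse) ||
        any(c(nUniverse, nFlaggedUniverse, nSelected,
            nFlaggedSelected) < 0))
        stop("inconsistent counts for the hypergeometric test")
    phyper(nFlaggedSelected - 1, nFlaggedUniverse,
        nUniverse - nFlaggedUniverse, nSelected, lower.tail = FALSE)
}

#' Sweep window-peak enrichment over many ChIP-seq experiments
#'
#' Runs [windowPeakOverlap()] plus [hypergeometricEnrichment()] for each
#' peak set of a named list (one entry per ChIP-seq experiment) and
#' reports the raw enrichment p-values with BH-adjusted values across
#' the sweep.
#'
#' @param cpgs Probe table as in [windowPeakOverlap()] (the universe).
#' @param sigCpgs Character vector of significant CpG ids.
#' @param peakSets Named list of peak sets (GRanges or BED-like
#'   data.frames).
#' @param window Window width in bp (default 200).
#'
#' @return A [S4Vectors::DataFrame] with one row per experiment:
#'   \code{experiment}, \code{n_flagged}, \code{n_flagged_sig},
#'   \code{p_value}, \code{q_value}.
#' @export
peakEnrichmentSweep <- function(cpgs, sigCpgs, peakSets, window = 200) {
    cpgs <- as.data.frame(cpgs)
    sig <- intersect(sigCpgs, cpgs$cpg_id)
    rows <- lapply(names(peakSets), function(nm) {
        flags <- suppressWarnings(windowPeakOverlap(cpgs,
            peakSets[[nm]], window = window))
        DataFrame(experiment = nm,
            n_flagged = sum(flags),
            n_flagged_sig = sum(flags[sig]),
            p_value = hypergeometricEnrichment(nrow(cpgs), sum(flags),
                length(sig), sum(flags[sig])))
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhFDR(out$p_value)
    out
}

#' Probe-bias-corrected gene-set enrichment
#'
#' Array probes are unevenly distributed over genes, so a gene with many
#' CpGs is more likely to be "hit" by a significant CpG by chance alone.
#' A gene is hit when at least one of its CpGs is significant; for each
#' gene set the observed hit count is compared with a resampling null in
#' which the same total number of hit genes is drawn without replacement
#' with probability proportional to each gene's probe count.  P-values
#' use the add-one correction \code{(1 + #\{null >= observed\}) /
#' (1 + nResamples)}.
#'
#' @param sigCpgs Character vector of significant CpG ids.
#' @param allCpgs Character vector of all tested CpG ids (the universe).
#' @param annotation \code{data.frame}/\code{DataFrame} with columns
#'   \code{cpg_id} and \code{gene_symbols} (semicolon-joined when a probe
#'   maps to several genes).
#' @param geneSets Named list of character vectors of gene symbols.
#' @param nResamples Number of null draws (default 1000).
#' @param seed Optional seed; the caller's RNG state is restored.
#'
#' @return A [S4Vectors::DataFrame] with one row per usable set:
#'   \code{set}, \code{n_genes}, \code{observed_hits},
#'   \code{expected_hits}, \code{p_value}.  Sets with no annotated gene
#'   are skipped with a warning.
#' @export
probeBiasGenesetTest <- function(sigCpgs, allCpgs, annotation, geneSets,
    nResamples = 1000, seed = NULL) {
    annotation <- as.data.frame(annotation)
    annotation <- annotation[annotation$cpg_id %in% allCpgs, , drop = FALSE]
    genesPerCpg <- strsplit(as.character(annotation$gene_symbols), ";",
        fixed = TRUE)
    long <- data.frame(
        cpg_id = rep(annotation$cpg_id, lengths(genesPerCpg)),
        gene = unlist(genesPerCpg), stringsAsFactors = FALSE)
    long <- long[!is.na(long$gene) & long$gene != "", , drop = FALSE]
    probeCount <- table(long$gene)
    genes <- names(probeCount)
    hitGenes <- unique(long$gene[long$cpg_id %in% sigCpgs])
    h <- length(hitGenes)
    usable <- vapply(geneSets, function(s) length(intersect(s, genes)) > 0,
        logical(1))
    if (any(!usable))
        warning("skipping gene sets with no annotated genes: ",
            paste(names(geneSets)[!usable], collapse = ", "))
    geneSets <- geneSets[usable]
    if (length(geneSets) == 0 || h == 0)
        return(DataFrame(set = character(), n_genes = integer(),
            observed_hits = integer(), expected_hits = numeric(),
            p_value = numeric()))
    member <- vapply(geneSets, function(s) genes %in% s,
        logical(length(genes)))
    obs <- colSums(member[match(hitGenes, genes), , drop = FALSE])
    .localSeed(seed)
    w <- as.numeric(probeCount)
    nullCounts <- matrix(0L, nResamples, length(geneSets))
    for (r in seq_len(nResamples)) {
        draw <- sample.int(length(genes), h, replace = FALSE, prob = w)
        nullCounts[r, ] <- colSums(member[draw, , drop = FALSE])
    }
    pv <- (1 + colSums(nullCounts >= rep(obs, each = nResamples))) /
        (1 + nResamples)
    DataFrame(set = names(geneSets),
        n_genes = colSums(member),
        observed_hits = as.integer(obs),
        expected_hits = colMeans(nullCounts),
        p_value = pv)
}

#' Overlap test against a published CpG or gene list
#'
#' Two-sided Fisher exact test of membership in a selected set (for
#' example the progression-associated CpGs) versus a published marker
#' list, within an explicit universe.  When the published results come
#' from a smaller platform, pass its probe content as
#' \code{restrictTo}: the universe, selection and list are intersected
#' with it before testing.
#'
#' @param selected Character vector (e.g. progression CpGs or genes).
#' @param published Character vector, the external list.
#' @param universe Character vector of all eligible items.
#' @param restrictTo Optional character vector restricting the universe
#'   (platform content).
#'
#' @return A list with \code{overlap}, \code{table} (2x2),
#'   \code{odds_ratio} and \code{p_value}.
#' @export
listOverlapTest <- function(selected, published, universe,
    restrictTo = NULL) {
    if (!is.null(restrictTo)) {
        universe <- intersect(universe, restrictTo)
        selected <- intersect(selected, restrictTo)
        published <- intersect(published, restrictTo)
    }
    published <- intersect(published, universe)
    if (length(published) == 0)
        stop("published list is disjoint from the universe; ",
            "wrong universe?")
    selected <- intersect(selected, universe)
    inSel <- universe %in% selected
    inPub <- universe %in% published
    tab <- matrix(c(sum(inSel & inPub), sum(inSel & !inPub),
        sum(!inSel & inPub), sum(!inSel & !inPub)), 2, byrow = TRUE,
        dimnames = list(c("selected", "not_selected"),
            c("published", "not_published")))
    ft <- fisher.test(tab)
    list(overlap = tab[1, 1], table = tab,
        odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
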