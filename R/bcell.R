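## Comparison of progression-associated CpGs with naive and memory
## B-cell reference methylomes: +/-10% group-mean difference calls,
## three-way overlap enrichment, direction concordance and hierarchical
## similarity clustering.

.groupMeans <- function(bm) rowMeans(betaValues(bm), na.rm = TRUE)

#' Group-mean beta differences between naive, memory and first CLL sample
#'
#' Per CpG, computes the three pairwise differences of group means --
#' memory minus naive, CLL(t1) minus naive, CLL(t1) minus memory -- and
#' flags each pair whose absolute difference is at least the threshold
#' (default 0.10, the "+/-10%" rule on the beta scale).
#'
#' @param naive,memory [BetaMatrix()] objects of reference B cells.
#' @param cllT1 A \code{BetaMatrix} of the first-time-point CLL samples.
#' @param threshold Absolute group-mean difference required for a flag.
#'
#' @return A [S4Vectors::DataFrame] with \code{cpg_id}, the three deltas
#'   (\code{delta_naive_memory}, \code{delta_naive_cll1},
#'   \code{delta_memory_cll1}), the three \code{flag_*} indicators and
#'   the three \code{dir_*} signs.
#' @export
groupwiseDeltas <- function(naive, memory, cllT1, threshold = 0.10) {
    for (bm in list(naive, memory, cllT1))
        if (ncol(bm) == 0) stop("empty sample group")
    shared <- Reduce(intersect, list(rownames(naive), rownames(memory),
        rownames(cllT1)))
    if (length(shared) == 0) stop("no shared CpGs across the groups")
    mN <- .groupMeans(naive[shared, ])
    mM <- .groupMeans(memory[shared, ])
    mC <- .groupMeans(cllT1[shared, ])
    d1 <- unname(mM - mN)
    d2 <- unname(mC - mN)
    d3 <- unname(mC - mM)
    DataFrame(cpg_id = shared,
        delta_naive_memory = d1, delta_naive_cll1 = d2,
        delta_memory_cll1 = d3,
        flag_naive_memory = abs(d1) >= threshold,
        flag_naive_cll1 = abs(d2) >= threshold,
        flag_memory_cll1 = abs(d3) >= threshold,
        dir_naive_memory = sign(d1), dir_naive_cll1 = sign(d2),
        dir_memory_cll1 = sign(d3))
}

#' Enrichment of progression CpGs among cell-type-differing CpGs
#'
#' For each pairwise comparison (naive vs memory, naive vs CLL, memory vs
#' CLL), tests by upper-tail hypergeometric whether progression CpGs --
#' and separately their H3K27me3-flagged stratum -- are over-represented
#' among the CpGs differing by at least 10% between the two groups.  The
#' universe is all CpGs in the comparison table.
#'
#' @param comparison Output of [groupwiseDeltas()].
#' @param progressionCpgs Character vector of progression CpG ids.
#' @param h3k27me3Cpgs Optional character vector defining the flagged
#'   stratum (its intersection with \code{progressionCpgs} is tested).
#'
#' @return A [S4Vectors::DataFrame] with one row per (pair, stratum):
#'   \code{pair}, \code{stratum}, \code{n_differing}, \code{n_selected},
#'   \code{overlap}, \code{p_value}.  An empty differing set yields
#'   \code{p = 1} with a warning.
#' @export
overlapEnrichmentThreeWay <- function(comparison, progressionCpgs,
    h3k27me3Cpgs = NULL) {
    universe <- comparison$cpg_id
    strata <- list(all = intersect(progressionCpgs, universe))
    if (!is.null(h3k27me3Cpgs))
        strata$h3k27me3 <- intersect(intersect(progressionCpgs,
            h3k27me3Cpgs), universe)
    pairs <- c(naive_memory = "flag_naive_memory",
        naive_cll1 = "flag_naive_cll1", memory_cll1 = "flag_memory_cll1")
    rows <- list()
    for (pn in names(pairs)) {
        differing <- universe[comparison[[pairs[pn]]]]
        if (length(differing) == 0)
            warning("no CpGs differ for pair ", pn, "; p = 1")
        for (sn in names(strata)) {
            sel <- strata[[sn]]
            ov <- length(intersect(sel, differing))
            p <- if (length(differing) == 0) 1 else
                hypergeometricEnrichment(length(universe),
                    length(differing), length(sel), ov)
            rows[[paste(pn, sn)]] <- DataFrame(pair = pn, stratum = sn,
                n_differing = length(differing),
                n_selected = length(sel), overlap = ov, p_value = p)
        }
    }
    do.call(rbind, unname(rows))
}

#' Direction concordance between progression and cell-type differences
#'
#' Among CpGs that are progression-associated and also differ (>= 10%)
#' in a given cell-type comparison, the percentage whose progression
#' delta has the same sign as the comparison delta ("both increase or
#' both decrease").  Zero deltas are excluded from the denominator.
#'
#' @param progressionDeltas Named numeric vector of per-CpG progression
#'   changes (e.g. median paired delta).
#' @param comparison Output of [groupwiseDeltas()].
#' @param pair One of \code{"naive_memory"}, \code{"naive_cll1"},
#'   \code{"memory_cll1"}.
#' @param stratum Optional character vector of CpG ids restricting the
#'   comparison (e.g. the H3K27me3-flagged progression CpGs).
#'
#' @return A list with \code{pair}, \code{stratum_size},
#'   \code{n_overlap} and \code{pct_same_direction} (NA with a warning
#'   when the overlap is empty).
#' @export
directionConcordance <- function(progressionDeltas, comparison,
    pair = c("naive_memory", "naive_cll1", "memory_cll1"),
    stratum = NULL) {
    pair <- match.arg(pair)
    flag <- comparison[[paste0("flag_", pair)]]
    differing <- comparison$cpg_id[flag]
    ids <- intersect(names(progressionDeltas), differing)
    if (!is.null(stratum)) ids <- intersect(ids, stratum)
    compDelta <- setNames(comparison[[paste0("delta_", pair)]],
        comparison$cpg_id)[ids]
    progDelta <- progressionDeltas[ids]
    keep <- progDelta != 0 & compDelta != 0
    if (sum(keep) == 0) {
        warning("empty overlap; concordance undefined")
        return(list(pair = pair, stratum_size = length(stratum),
            n_overlap = 0L, pct_same_direction = NA_real_))
    }
    same <- sign(progDelta[keep]) == sign(compDelta[keep])
    list(pair = pair, stratum_size = length(stratum),
        n_overlap = sum(keep),
        pct_same_direction = 100 * mean(same))
}

#' Similarity clustering of samples with B-cell references
#'
#' Average-linkage hierarchical clustering on Euclidean distance over a
#' CpG subset (typically the progression-associated CpGs), combining CLL
#' samples with naive and memory reference profiles, plus a per-sample
#' nearest-reference call (naive vs memory) by mean distance to each
#' reference group.
#'
#' @param samples A [BetaMatrix()] of CLL samples.
#' @param naive,memory \code{BetaMatrix} reference groups.
#' @param cpgs Optional CpG ids to restrict to (default: CpGs shared by
#'   all three objects).
#'
#' @return A list with \code{tree} (an [ape::phylo]), \code{hclust},
#'   \code{nearest} (DataFrame of per-sample calls) and
#'   \code{degenerate} (TRUE when all distances are zero).
#' @export
similarityClustering <- function(samples, naive, memory, cpgs = NULL) {
    if (ncol(samples) < 2) stop("need at least 2 samples")
    shared <- Reduce(intersect, list(rownames(samples), rownames(naive),
        rownames(memory)))
    if (!is.null(cpgs)) shared <- intersect(shared, cpgs)
    if (length(shared) == 0) stop("no shared CpGs to cluster on")
    S <- betaValues(samples)[shared, , drop = FALSE]
    Nn <- betaValues(naive)[shared, , drop = FALSE]
    M <- betaValues(memory)[shared, , drop = FALSE]
    all <- cbind(S, Nn, M)
    d <- dist(t(all))
    degenerate <- all(d == 0)
    if (degenerate)
        warning("all pairwise distances are zero; degenerate tree")
    hc <- hclust(d, method = "average")
    meanDistTo <- function(x, ref)
        mean(sqrt(colSums((ref - x)^2)))
    nearest <- vapply(seq_len(ncol(S)), function(j) {
        dn <- meanDistTo(S[, j], Nn)
        dm <- meanDistTo(S[, j], M)
        if (dm <= dn) "memory" else "naive"
    }, character(1))
    list(tree = ape::as.phylo(hc), hclust = hc,
        nearest = DataFrame(sample_id = colnames(S), nearest = nearest),
        degenerate = degenerate)
}
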