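## Synthetic cohort generation with known ground truth.
##
## The genetic generator draws subclonal architectures per patient,
## converts clone prevalences and purity to expected variant allele
## fractions (heterozygous, diploid: VAF = purity * prevalence / 2), and
## emits binomial read counts at Poisson depths for the exome (~100x) and
## amplicon (~850x) regimes.  The methylation generator mixes five
## cell-type reference profiles with per-sample compositions, plants
## progression effects at the second time point, and assigns H3K27me3
## flags enriched at planted CpGs.

.rdirichlet1 <- function(k, alpha = 1) {
    g <- stats::rgamma(k, alpha)
    g / sum(g)
}

#' Simulate a cell-type reference panel
#'
#' Builds marker CpGs for each of the five cell types: at its own
#' markers a cell type has beta \code{highBeta} while all other types
#' have \code{lowBeta}, the classic differentially methylated marker
#' structure that makes deconvolution identifiable.
#'
#' @param nMarkersPerType Markers per cell type (default 10).
#' @param highBeta,lowBeta Beta value of the owning/other cell types.
#' @param seed Optional seed (caller's RNG state restored).
#'
#' @return A [ReferencePanel()].
#' @export
#' @examples
#' simulateReferencePanel(2)
simulateReferencePanel <- function(nMarkersPerType = 10,
    highBeta = 0.85, lowBeta = 0.10, seed = NULL) {
    .localSeed(seed)
    types <- cellTypeNames()
    n <- nMarkersPerType * length(types)
    prof <- matrix(lowBeta, n, length(types),
        dimnames = list(paste0("mk_", rep(types, each = nMarkersPerType),
            "_", seq_len(nMarkersPerType)), types))
    for (i in seq_along(types))
        prof[(i - 1) * nMarkersPerType + seq_len(nMarkersPerType),
            types[i]] <- highBeta
    # small jitter so markers are not exactly collinear
    prof <- prof + matrix(runif(length(prof), -0.02, 0.02), n)
    prof <- pmin(pmax(prof, 0), 1)
    ReferencePanel(prof)
}

#' Simulate the subclonal architecture of one patient
#'
#' Draws 2-9 subclones and constructs prevalences at the two time points
#' that realize the requested somatic-evolution category: one subclone
#' rising and one falling by \code{prevalenceShift} (evolving), two
#' rising (expanding), two falling (contracting) or no change (static).
#' Variants are split between the trunk and the subclones so that the
#' moving clones carry at least two variants each.
#'
#' @param patientId Patient identifier.
#' @param category Planted category.
#' @param nVariants Number of somatic variants.
#' @param prevalenceShift Prevalence change of moving clones (default
#'   0.3; must leave the fraction vectors on the simplex).
#' @param purityT1,purityT2 Tumor purities.
#' @param nClones Number of subclones (default: drawn from 2..9).
#' @param fracTrunk Fraction of variants assigned to the trunk.
#'
#' @return A [CloneStructure()].
#' @export
simulateCloneStructure <- function(patientId,
    category = c("static", "expanding", "evolving", "contracting"),
    nVariants = 25, prevalenceShift = 0.3, purityT1 = 0.85,
    purityT2 = 0.85, nClones = NULL, fracTrunk = 0.4) {
    category <- match.arg(category)
    if (is.null(nClones)) nClones <- sample(2:9, 1)
    if (nClones < 2 || nClones > 9)
        stop("2-9 subclones are supported")
    if (prevalenceShift <= 0 || prevalenceShift > 0.3)
        stop("prevalenceShift must lie in (0, 0.3] so fractions stay ",
            "on the simplex")
    k <- nClones
    lowBase <- 0.05
    othersMass <- 0.25
    others <- if (k > 2) .rdirichlet1(k - 2) * othersMass else numeric(0)
    f1 <- f2 <- c(lowBase, lowBase, others)
    if (category == "evolving") {
        f1[2] <- lowBase + prevalenceShift
        f2[1] <- lowBase + prevalenceShift
    } else if (category == "expanding") {
        f2[1] <- lowBase + prevalenceShift
        f2[2] <- lowBase + prevalenceShift
    } else if (category == "contracting") {
        f1[1] <- lowBase + prevalenceShift
        f1[2] <- lowBase + prevalenceShift
    }
    nTrunk <- max(1L, round(fracTrunk * nVariants))
    nSub <- nVariants - nTrunk
    if (nSub < 4)
        stop("need at least 4 subclonal variants; increase nVariants")
    assign <- c(rep(0L, nTrunk),
        rep(seq_len(k), length.out = nSub))
    CloneStructure(patientId, f1, f2, assign, purityT1, purityT2)
}

#' Simulate a genetic cohort with known subclonal dynamics
#'
#' For each patient, draws a [CloneStructure()] realizing a planted
#' somatic-evolution category, then emits [TriSampleCounts()] at the
#' exome depth (for somatic calling) and the amplicon depth (for drift
#' testing) from the same architectures.  Somatic sites have germline
#' alternate fraction 0; additional germline sites are emitted as
#' hom-ref, het and hom-alt (alt fractions 0, 0.5, 1) identically across
#' the three samples.  Per-site depths are Poisson around the configured
#' means with a floor of one read.
#'
#' @param config A [SimulationConfig()]; \code{config@seed} drives all
#'   randomness (the caller's RNG state is restored).
#' @param categories Optional character vector of planted categories
#'   (recycled over patients).  Default: sampled from static, expanding
#'   and evolving with weights 9/19, 5/19, 5/19.
#' @param prevalenceShift Prevalence change of moving subclones.
#' @param nClones Optional fixed subclone count (default: 2..9 per
#'   patient).
#'
#' @return A list with \code{exome} and \code{amplicon}
#'   ([TriSampleCounts()]), \code{truth} (clone structures, somatic site
#'   ids, per-variant drift directions, per-patient categories) and
#'   \code{config}.
#' @export
#' @examples
#' sim <- simulateGeneticCohort(SimulationConfig(nPatients = 2, seed = 7))
#' head(as.data.frame(sim$amplicon))
#' sim$truth$true_category
simulateGeneticCohort <- function(config, categories = NULL,
    prevalenceShift = 0.3, nClones = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .localSeed(config@seed)
    nP <- config@nPatients
    if (is.null(categories))
        categories <- sample(c("static", "expanding", "evolving"), nP,
            replace = TRUE, prob = c(9, 5, 5) / 19)
    categories <- rep_len(categories, nP)
    pids <- sprintf("P%02d", seq_len(nP))
    structures <- list()
    rows <- list()
    truthDir <- character(0)
    somaticSites <- character(0)
    trueCat <- setNames(character(nP), pids)
    drawCounts <- function(evaf, meanDepth) {
        d <- pmax(1L, rpois(length(evaf), meanDepth))
        alt <- rbinom(length(evaf), d, evaf)
        cbind(ref = d - alt, alt = alt)
    }
    for (i in seq_len(nP)) {
        cs <- simulateCloneStructure(pids[i], categories[i],
            nVariants = config@nVariants,
            prevalenceShift = prevalenceShift,
            purityT1 = config@purityT1, purityT2 = config@purityT2,
            nClones = nClones)
        structures[[pids[i]]] <- cs
        ev <- expectedVAF(cs)
        nV <- nrow(ev)
        dir <- ifelse(ev[, "t2"] > ev[, "t1"] + 1e-9, "up",
            ifelse(ev[, "t2"] < ev[, "t1"] - 1e-9, "down", "none"))
        nUp <- sum(dir == "up")
        nDown <- sum(dir == "down")
        trueCat[pids[i]] <- if (nUp >= 1 && nDown >= 1) "evolving"
            else if (nUp >= 2 && nDown == 0) "expanding"
            else if (nUp + nDown <= 1) "static" else "contracting"
        gAf <- rep(c(0, 0.5, 1),
            length.out = config@nGermlineSites)
        siteIds <- c(sprintf("%s_s%03d", pids[i], seq_len(nV)),
            sprintf("%s_g%03d", pids[i], seq_len(config@nGermlineSites)))
        somaticSites <- c(somaticSites, siteIds[seq_len(nV)])
        truthDir <- c(truthDir, setNames(dir, siteIds[seq_len(nV)]))
        afG <- c(rep(0, nV), gAf)
        af1 <- c(ev[, "t1"], gAf)
        af2 <- c(ev[, "t2"], gAf)
        for (regime in c("exome", "amplicon")) {
            depth <- if (regime == "exome") config@depthExome else
                config@depthAmplicon
            g <- drawCounts(afG, depth)
            t1 <- drawCounts(af1, depth)
            t2 <- drawCounts(af2, depth)
            rows[[paste(pids[i], regime)]] <- data.frame(
                site_id = siteIds, patient_id = pids[i],
                chrom = "chr1",
                pos = seq_along(siteIds) + (i - 1L) * 10000L,
                ref_count_g = g[, "ref"], alt_count_g = g[, "alt"],
                ref_count_t1 = t1[, "ref"], alt_count_t1 = t1[, "alt"],
                ref_count_t2 = t2[, "ref"], alt_count_t2 = t2[, "alt"],
                regime = regime, stringsAsFactors = FALSE)
        }
    }
    all <- do.call(rbind, unname(rows))
    mk <- function(regime) {
        d <- all[all$regime == regime,
            setdiff(colnames(all), "regime"), drop = FALSE]
        rownames(d) <- NULL
        TriSampleCounts(d)
    }
    list(exome = mk("exome"), amplicon = mk("amplicon"),
        truth = list(clone_structures = structures,
            true_somatic_sites = somaticSites,
            true_drift_directions = truthDir,
            true_category = trueCat),
        config = config)
}

## effect-magnitude distribution: scaled Beta(1.2, 2.772) has median
## matching (effectMedian - effectMin) / (effectMax - effectMin) for the
## default 0.029 within [0.005, 0.095]
.effectShapes <- c(1.2, 2.772)

#' Simulate a methylation cohort with planted progression effects
#'
#' Each sample's beta vector is built as reference profiles times the
#' sample's cell-type composition, plus -- at the second time point only
#' -- a planted progression delta at the chosen progression CpGs, plus
#' Gaussian noise, clamped to \code{[0,1]}.  B-cell fraction rises
#' slightly between time points (the leukemia expanding relative to
#' normal cells), so composition adjustment has real work to do.
#' Planted effect magnitudes have median \code{config@effectMedian} and
#' range \code{[effectMin, effectMax]}; a fraction \code{fracIncrease}
#' are increases.  H3K27me3 flags are assigned so that planted CpGs are
#' enriched under the flag at odds ratio \code{config@flagOddsRatio}.
#'
#' @param config A [SimulationConfig()].
#' @param panel Optional [ReferencePanel()]; simulated when absent.  The
#'   panel's marker CpGs are included as array rows (progression effects
#'   are never planted on markers).
#'
#' @return A list with \code{beta} (a [BetaMatrix()] with both
#'   timepoints), \code{panel}, \code{annotation} (cpg_id, chrom, pos,
#'   gene_symbols, h3k27me3_flag), \code{peaks} (synthetic BED-like
#'   peak table consistent with the flags), \code{truth}
#'   (\code{true_compositions}, \code{true_progression_cpgs},
#'   \code{true_directions}, \code{true_effects}) and \code{config}.
#' @export
#' @examples
#' sim <- simulateMethylationCohort(SimulationConfig(nPatients = 6,
#'     nCpgs = 300, seed = 3))
#' sim$beta
simulateMethylationCohort <- function(config, panel = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .localSeed(config@seed)
    if (is.null(panel)) panel <- simulateReferencePanel()
    types <- cellTypeNames()
    mk <- profileMatrix(panel)
    nOther <- config@nCpgs
    otherIds <- sprintf("cg%06d", seq_len(nOther))
    base <- rbeta(nOther, 0.4, 0.4)
    prof <- matrix(base, nOther, length(types),
        dimnames = list(otherIds, types))
    typed <- runif(nOther) < 0.2   # CpGs with real cell-type differences
    jitter <- matrix(rnorm(sum(typed) * length(types), 0, 0.08),
        sum(typed))
    prof[typed, ] <- pmin(pmax(prof[typed, ] + jitter, 0), 1)
    profiles <- rbind(mk, prof)
    cpgIds <- rownames(profiles)

    # progression effects are planted at CpGs with beta-scale headroom:
    # a saturated CpG (beta near 0 or 1) cannot express a modest planted
    # change, mirroring how observed progression changes concentrate at
    # intermediate-methylation sites
    nProg <- round(config@fracProgressionCpgs * nOther)
    candidates <- otherIds[base > 0.15 & base < 0.85]
    if (length(candidates) < nProg)
        stop("too few intermediate-methylation CpGs to plant effects; ",
            "increase nCpgs")
    progCpgs <- sample(candidates, nProg)
    dirUp <- runif(nProg) < config@fracIncrease
    eff <- config@effectMin + (config@effectMax - config@effectMin) *
        rbeta(nProg, .effectShapes[1], .effectShapes[2])
    effects <- setNames(ifelse(dirUp, eff, -eff), progCpgs)

    p0 <- config@flagBaseline
    odds1 <- config@flagOddsRatio * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    flagP <- ifelse(cpgIds %in% progCpgs, p1, p0)
    flags <- runif(length(cpgIds)) < flagP

    nP <- config@nPatients
    pids <- sprintf("P%02d", seq_len(nP))
    sampleIds <- c(paste0(pids, "_t1"), paste0(pids, "_t2"))
    W <- matrix(0, 2 * nP, length(types),
        dimnames = list(sampleIds, types))
    beta <- matrix(0, length(cpgIds), 2 * nP,
        dimnames = list(cpgIds, sampleIds))
    for (i in seq_len(nP)) {
        wB1 <- runif(1, 0.7, 0.9)
        wB2 <- min(0.98, wB1 + runif(1, 0, 0.08))
        restShape <- .rdirichlet1(length(types) - 1)
        w1 <- c(wB1, (1 - wB1) * restShape)
        w2 <- c(wB2, (1 - wB2) * restShape)
        W[i, ] <- w1
        W[nP + i, ] <- w2
        mu1 <- as.vector(profiles %*% w1)
        mu2 <- as.vector(profiles %*% w2)
        mu2[match(progCpgs, cpgIds)] <-
            mu2[match(progCpgs, cpgIds)] + effects
        noise <- function(mu) pmin(1, pmax(0,
            mu + rnorm(length(mu), 0, config@noiseSd)))
        beta[, i] <- noise(mu1)
        beta[, nP + i] <- noise(mu2)
    }
    bm <- BetaMatrix(beta,
        patientId = rep(pids, 2),
        timepoint = rep(c("t1", "t2"), each = nP),
        sortedFlag = FALSE)

    genePool <- sprintf("G%04d", seq_len(max(50, round(nOther / 8))))
    geneOf <- sample(genePool, length(cpgIds), replace = TRUE,
        prob = rexp(length(genePool)) + 0.1)
    # probes spaced >= 300 bp so a probe's synthetic peak cannot fall
    # into a neighboring probe's 200 bp window
    pos <- cumsum(sample(300:2000, length(cpgIds), replace = TRUE))
    annotation <- DataFrame(cpg_id = cpgIds, chrom = "chr1", pos = pos,
        gene_symbols = geneOf, h3k27me3_flag = flags)
    flaggedPos <- pos[flags]
    peaks <- data.frame(chrom = "chr1",
        start = flaggedPos + 50L, end = flaggedPos + 90L)

    list(beta = bm, panel = panel, profiles = profiles,
        annotation = annotation, peaks = peaks,
        truth = list(true_compositions = W,
            true_progression_cpgs = progCpgs,
            true_directions = ifelse(dirUp, "up", "down"),
            true_effects = effects),
        config = config)
}

#' Simulate naive and memory B-cell reference methylomes
#'
#' Builds two reference groups from the B-cell profile of a methylation
#' simulation: memory B cells follow the B-cell profile, while naive B
#' cells are shifted at the planted progression CpGs opposite to the
#' planted progression direction (so progression moves CLL methylation
#' in the naive-to-memory direction, the concordance structure the
#' comparison analyses look for) and at a set of additional CpGs in
#' random directions.
#'
#' @param sim Output of [simulateMethylationCohort()].
#' @param nPerGroup Samples per reference group (default 6).
#' @param refDiff Beta difference between naive and memory at differing
#'   CpGs (default 0.15).
#' @param concordantFrac Fraction of planted CpGs given a naive/memory
#'   difference concordant with the planted progression direction.
#' @param noiseSd Per-sample noise (default: the simulation's).
#' @param seed Optional seed.
#'
#' @return A list with \code{naive} and \code{memory} ([BetaMatrix()]).
#' @export
simulateBCellPanels <- function(sim, nPerGroup = 6, refDiff = 0.15,
    concordantFrac = 0.9, noiseSd = NULL, seed = NULL) {
    .localSeed(seed)
    if (is.null(noiseSd)) noiseSd <- sim$config@noiseSd
    cfgIds <- rownames(betaValues(sim$beta))
    # memory B cells follow the pure B-cell profile of the array
    memMu <- setNames(sim$profiles[cfgIds, "B"], cfgIds)
    naiMu <- memMu
    prog <- sim$truth$true_progression_cpgs
    eff <- sim$truth$true_effects
    conc <- runif(length(prog)) < concordantFrac
    shift <- ifelse(conc, -sign(eff), sign(eff)) * refDiff
    naiMu[prog] <- pmin(1, pmax(0, naiMu[prog] + shift))
    extra <- sample(setdiff(cfgIds, prog),
        max(10, round(0.02 * length(cfgIds))))
    naiMu[extra] <- pmin(1, pmax(0,
        naiMu[extra] + sample(c(-1, 1), length(extra), TRUE) * refDiff))
    draw <- function(mu, label) {
        m <- vapply(seq_len(nPerGroup), function(j)
            pmin(1, pmax(0, mu + rnorm(length(mu), 0, noiseSd))),
            numeric(length(mu)))
        dimnames(m) <- list(cfgIds, paste0(label, seq_len(nPerGroup)))
        BetaMatrix(m, patientId = colnames(m), timepoint = NA,
            sortedFlag = TRUE, group = label)
    }
    list(naive = draw(naiMu, "naive"), memory = draw(memMu, "memory"))
}

#' Simulate somatic copy-number segment calls
#'
#' Emits per-patient segment calls at recurrent CLL loci and elsewhere,
#' with the same event usually called at both time points (with small
#' boundary jitter) so that grouping has real work to do.
#'
#' @param nPatients Number of patients.
#' @param fracRecurrent Fraction of patients given at least one segment
#'   at a recurrent locus.
#' @param loci Recurrent-locus table (see [cllRecurrentLoci()]).
#' @param seed Optional seed.
#'
#' @return A \code{data.frame} of segments (\code{patient_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{copy_number},
#'   \code{confidence}, \code{timepoint}).
#' @export
simulateCNASegments <- function(nPatients, fracRecurrent = 13 / 19,
    loci = cllRecurrentLoci(), seed = NULL) {
    .localSeed(seed)
    pids <- sprintf("P%02d", seq_len(nPatients))
    recurrent <- runif(nPatients) < fracRecurrent
    rows <- list()
    for (i in seq_len(nPatients)) {
        if (recurrent[i]) {
            l <- loci[sample.int(nrow(loci), 1), ]
            len <- round(runif(1, 2e6, min(2e7, l$end - l$start)))
            s <- round(runif(1, l$start, l$end - len))
            for (tp in c("t1", "t2")) {
                j <- round(runif(2, 0, 5e4))
                rows[[paste(i, tp)]] <- data.frame(
                    patient_id = pids[i], chrom = l$chrom,
                    start = s + j[1], end = s + len + j[2],
                    copy_number = sample(c(1, 3), 1),
                    confidence = runif(1, 35, 100), timepoint = tp)
            }
        }
        if (runif(1) < 0.3) {    # occasional non-recurrent event
            s <- round(runif(1, 1e6, 1e8))
            rows[[paste(i, "other")]] <- data.frame(
                patient_id = pids[i], chrom = "chr5",
                start = s, end = s + round(runif(1, 1e6, 5e6)),
                copy_number = sample(c(1, 3), 1),
                confidence = runif(1, 35, 100),
                timepoint = sample(c("t1", "t2"), 1))
        }
    }
    if (length(rows) == 0)
        return(data.frame(patient_id = character(), chrom = character(),
            start = numeric(), end = numeric(), copy_number = numeric(),
            confidence = numeric(), timepoint = character()))
    out <- do.call(rbind, unname(rows))
    rownames(out) <- NULL
    out
}
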