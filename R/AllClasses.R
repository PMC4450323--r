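## Central S4 data containers.  BetaMatrix rides on SummarizedExperiment so
## the usual assay/colData machinery applies; allele-count tables ride on
## DFrame so they behave like ordinary Bioconductor tables.

#' The five leukocyte cell types used throughout
#'
#' Canonical order of the five cell types whose mixture makes up an
#' unsorted CLL blood sample: B cells, natural killer cells, CD4+ T cells,
#' CD8+ T cells and neutrophils.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' cellTypeNames()
cellTypeNames <- function() c("B", "NK", "CD4T", "CD8T", "Neutrophil")

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
    representation(
        nPatients = "integer",
        nVariants = "integer",
        nGermlineSites = "integer",
        depthExome = "numeric",
        depthAmplicon = "numeric",
        purityT1 = "numeric",
        purityT2 = "numeric",
        nCpgs = "integer",
        fracProgressionCpgs = "numeric",
        effectMedian = "numeric",
        effectMin = "numeric",
        effectMax = "numeric",
        fracIncrease = "numeric",
        noiseSd = "numeric",
        flagBaseline = "numeric",
        flagOddsRatio = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    frac <- c(
        purityT1 = object@purityT1, purityT2 = object@purityT2,
        fracProgressionCpgs = object@fracProgressionCpgs,
        fracIncrease = object@fracIncrease,
        flagBaseline = object@flagBaseline
    )
    bad <- frac < 0 | frac > 1
    if (any(bad))
        msg <- c(msg, paste0("fractions outside [0,1]: ",
            paste(names(frac)[bad], collapse = ", ")))
    if (object@depthExome <= 0 || object@depthAmplicon <= 0)
        msg <- c(msg, "sequencing depths must be positive")
    if (!(object@effectMin <= object@effectMedian &&
          object@effectMedian <= object@effectMax))
        msg <- c(msg, "need effectMin <= effectMedian <= effectMax")
    if (object@effectMin < 0 || object@effectMax > 1)
        msg <- c(msg, "effect sizes must lie in [0,1] on the beta scale")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be non-negative")
    if (object@nPatients < 1 || object@nVariants < 1 || object@nCpgs < 1)
        msg <- c(msg, "nPatients, nVariants and nCpgs must be >= 1")
    if (object@flagOddsRatio <= 0)
        msg <- c(msg, "flagOddsRatio must be positive")
    if (length(msg)) msg else TRUE
})

#' Simulation settings for synthetic cohorts
#'
#' Bundles every tunable of the synthetic cohort generator.  The defaults
#' describe the study design the package targets: 27 patients sampled at
#' two pre-treatment time points, exome sequencing at ~100x (the 75-150x
#' regime), amplicon validation sequencing at ~850x, and planted
#' progression effects on the methylation array whose signed changes are
#' increases in 77% of cases with median magnitude 0.029 (range
#' 0.005-0.095 beta units).
#'
#' @param nPatients Number of patients (paired samples per patient).
#' @param nVariants Somatic variants simulated per patient.
#' @param nGermlineSites Non-somatic (hom-ref/het/hom-alt) sites emitted
#'   per patient so that somatic calling has true negatives to reject.
#' @param depthExome,depthAmplicon Mean sequencing depths; per-site depths
#'   are Poisson around these means with a floor of 1 read.
#' @param purityT1,purityT2 Tumor cell fraction of each sample.
#' @param nCpgs Number of CpGs on the simulated array.
#' @param fracProgressionCpgs Fraction of CpGs given a planted progression
#'   effect at the second time point.
#' @param effectMedian,effectMin,effectMax Median and range of the planted
#'   absolute beta change.
#' @param fracIncrease Fraction of planted effects that are increases.
#' @param noiseSd Standard deviation of truncated-Gaussian beta noise.
#' @param flagBaseline Marginal H3K27me3 flag rate among unplanted CpGs.
#' @param flagOddsRatio Odds ratio by which planted CpGs are enriched
#'   under the H3K27me3 flag.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return A \code{SimulationConfig} object.
#' @export
#' @examples
#' cfg <- SimulationConfig(nPatients = 5, nCpgs = 500)
#' cfg
SimulationConfig <- function(nPatients = 27, nVariants = 25,
    nGermlineSites = 10, depthExome = 100, depthAmplicon = 850,
    purityT1 = 0.85, purityT2 = 0.85, nCpgs = 20000,
    fracProgressionCpgs = 0.01, effectMedian = 0.029, effectMin = 0.005,
    effectMax = 0.095, fracIncrease = 0.77, noiseSd = 0.02,
    flagBaseline = 0.2, flagOddsRatio = 3, seed = 1) {
    new("SimulationConfig",
        nPatients = as.integer(nPatients),
        nVariants = as.integer(nVariants),
        nGermlineSites = as.integer(nGermlineSites),
        depthExome = as.numeric(depthExome),
        depthAmplicon = as.numeric(depthAmplicon),
        purityT1 = as.numeric(purityT1),
        purityT2 = as.numeric(purityT2),
        nCpgs = as.integer(nCpgs),
        fracProgressionCpgs = as.numeric(fracProgressionCpgs),
        effectMedian = as.numeric(effectMedian),
        effectMin = as.numeric(effectMin),
        effectMax = as.numeric(effectMax),
        fracIncrease = as.numeric(fracIncrease),
        noiseSd = as.numeric(noiseSd),
        flagBaseline = as.numeric(flagBaseline),
        flagOddsRatio = as.numeric(flagOddsRatio),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  patients:", object@nPatients,
        " variants/patient:", object@nVariants, "\n")
    cat("  depths: exome", object@depthExome,
        "x, amplicon", object@depthAmplicon, "x\n")
    cat("  CpGs:", object@nCpgs, " planted fraction:",
        object@fracProgressionCpgs, "\n")
    cat("  effects: median", object@effectMedian, "range [",
        object@effectMin, ",", object@effectMax, "], increases",
        object@fracIncrease, "\n")
    cat("  noise sd:", object@noiseSd, " seed:", object@seed, "\n")
    invisible(NULL)
})

#' @rdname CloneStructure
#' @export
setClass("CloneStructure",
    representation(
        patientId = "character",
        fractionsT1 = "numeric",
        fractionsT2 = "numeric",
        variantClone = "integer",
        purityT1 = "numeric",
        purityT2 = "numeric",
        nesting = "character"
    )
)

setValidity("CloneStructure", function(object) {
    msg <- character()
    k <- length(object@fractionsT1)
    if (k != length(object@fractionsT2))
        msg <- c(msg, "time points must have the same number of clones")
    if (k < 2 || k > 9)
        msg <- c(msg, "2-9 subclones per patient are supported")
    for (fr in list(object@fractionsT1, object@fractionsT2)) {
        if (any(fr < 0))
            msg <- c(msg, "clone fractions must be non-negative")
        if (sum(fr) > 1 + 1e-8)
            msg <- c(msg, "clone fractions must sum to <= 1")
    }
    if (any(is.na(object@variantClone)) ||
        any(object@variantClone < 0 | object@variantClone > k))
        msg <- c(msg,
            "each variant must map to the trunk (0) or one subclone (1..k)")
    if (object@purityT1 < 0 || object@purityT1 > 1 ||
        object@purityT2 < 0 || object@purityT2 > 1)
        msg <- c(msg, "purity must lie in [0,1]")
    if (!object@nesting %in% c("independent", "linear"))
        msg <- c(msg, "nesting must be 'independent' or 'linear'")
    if (length(msg)) msg else TRUE
})

#' Subclonal architecture of one simulated patient
#'
#' Describes 2-9 subclones with cellular prevalences at the two time
#' points, the assignment of each somatic variant to the trunk (clone 0,
#' carried by all tumor cells) or to one subclone, and the tumor purity of
#' each sample.  Under \code{nesting = "independent"} the subclones are
#' disjoint cell populations and the residual mass is the ancestral clone;
#' under \code{"linear"} clone \code{i+1} is nested inside clone \code{i}
#' so a variant's prevalence is the summed fraction of its clone and all
#' deeper clones.
#'
#' @param patientId Patient identifier.
#' @param fractionsT1,fractionsT2 Numeric vectors of subclone cellular
#'   prevalences (one element per subclone, non-negative, sum <= 1).
#' @param variantClone Integer vector mapping each variant to clone 0
#'   (trunk) or a subclone index.
#' @param purityT1,purityT2 Tumor fractions in \code{[0,1]}.
#' @param nesting \code{"independent"} (default) or \code{"linear"}.
#'
#' @return A \code{CloneStructure} object.
#' @export
#' @examples
#' cs <- CloneStructure("P1", c(0.5, 0.2), c(0.2, 0.6), c(0L, 1L, 2L),
#'     purityT1 = 0.9, purityT2 = 0.9)
#' expectedVAF(cs)
CloneStructure <- function(patientId, fractionsT1, fractionsT2,
    variantClone, purityT1 = 0.85, purityT2 = 0.85,
    nesting = "independent") {
    new("CloneStructure", patientId = as.character(patientId),
        fractionsT1 = as.numeric(fractionsT1),
        fractionsT2 = as.numeric(fractionsT2),
        variantClone = as.integer(variantClone),
        purityT1 = as.numeric(purityT1), purityT2 = as.numeric(purityT2),
        nesting = nesting)
}

setMethod("show", "CloneStructure", function(object) {
    cat("CloneStructure for patient", object@patientId, "\n")
    cat("  subclones:", length(object@fractionsT1),
        " variants:", length(object@variantClone), "\n")
    cat("  prevalences t1:", paste(round(object@fractionsT1, 3),
        collapse = " "), "\n")
    cat("  prevalences t2:", paste(round(object@fractionsT2, 3),
        collapse = " "), "\n")
    cat("  purity:", object@purityT1, "->", object@purityT2,
        " nesting:", object@nesting, "\n")
    invisible(NULL)
})

.triSampleCols <- c("site_id", "patient_id", "chrom", "pos",
    "ref_count_g", "alt_count_g", "ref_count_t1", "alt_count_t1",
    "ref_count_t2", "alt_count_t2")

#' @rdname TriSampleCounts
#' @export
setClass("TriSampleCounts", contains = "DFrame")

setValidity("TriSampleCounts", function(object) {
    msg <- character()
    missing <- setdiff(.triSampleCols, colnames(object))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    cnt <- as.matrix(as.data.frame(object[, grep("_count_",
        colnames(object), value = TRUE)]))
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "read counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Per-site allele counts for germline and two tumor time points
#'
#' One row per variant site with ref/alt read counts in the germline
#' sample and in the tumor samples from the first and second time point.
#' This is the substrate for somatic calling (2x3 permutation chi-square
#' across the three samples) and drift testing (2x2 Fisher between the
#' tumor samples).
#'
#' @param x A \code{data.frame} or \code{DataFrame} with columns
#'   \code{site_id}, \code{patient_id}, \code{chrom}, \code{pos} (1-based)
#'   and the six count columns \code{ref_count_g}, \code{alt_count_g},
#'   \code{ref_count_t1}, \code{alt_count_t1}, \code{ref_count_t2},
#'   \code{alt_count_t2}.
#'
#' @return A \code{TriSampleCounts} object (a \code{DFrame} subclass).
#' @export
#' @examples
#' tsc <- TriSampleCounts(data.frame(site_id = "s1", patient_id = "P1",
#'     chrom = "chr1", pos = 100, ref_count_g = 50, alt_count_g = 0,
#'     ref_count_t1 = 40, alt_count_t1 = 10,
#'     ref_count_t2 = 30, alt_count_t2 = 20))
#' tsc
TriSampleCounts <- function(x) {
    df <- as(as.data.frame(x), "DataFrame")
    for (cc in grep("_count_", colnames(df), value = TRUE))
        df[[cc]] <- as.integer(df[[cc]])
    new("TriSampleCounts", df)
}

#' @rdname BetaMatrix
#' @export
setClass("BetaMatrix", contains = "SummarizedExperiment")

setValidity("BetaMatrix", function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        return("a 'beta' assay is required")
    b <- assay(object, "beta")
    if (any(b < -1e-12 | b > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "beta values must lie in [0,1]")
    need <- c("patient_id", "timepoint")
    missing <- setdiff(need, colnames(colData(object)))
    if (length(missing))
        msg <- c(msg, paste("colData lacks:", paste(missing,
            collapse = ", ")))
    else {
        tp <- colData(object)$timepoint
        if (!all(tp %in% c("t1", "t2") | is.na(tp)))
            msg <- c(msg, "timepoint must be 't1', 't2' or NA")
    }
    if (length(msg)) msg else TRUE
})

#' CpG-by-sample methylation beta matrix
#'
#' A \code{SummarizedExperiment} subclass holding methylation fractions
#' (beta values in \code{[0,1]}) with CpGs as rows and samples as
#' columns.  Column metadata records \code{patient_id}, \code{timepoint}
#' (\code{"t1"}, \code{"t2"} or \code{NA} for reference samples),
#' \code{sorted_flag} and optionally a \code{group} label (for example
#' \code{"naive"} or \code{"memory"} reference cells).
#'
#' @param beta Numeric matrix of beta values, CpG ids as rownames and
#'   sample ids as colnames.
#' @param patientId Character vector, one entry per column.
#' @param timepoint Character vector of \code{"t1"}/\code{"t2"} (or NA).
#' @param sortedFlag Logical vector; were the cells sorted?
#' @param group Optional character vector of group labels.
#'
#' @return A \code{BetaMatrix} object.
#' @export
#' @examples
#' b <- matrix(runif(20), 5, 4,
#'     dimnames = list(paste0("cg", 1:5), paste0("S", 1:4)))
#' bm <- BetaMatrix(b, patientId = c("P1", "P1", "P2", "P2"),
#'     timepoint = c("t1", "t2", "t1", "t2"))
#' betaValues(bm)[1:2, ]
BetaMatrix <- function(beta, patientId, timepoint = NA_character_,
    sortedFlag = FALSE, group = NA_character_) {
    beta <- as.matrix(beta)
    n <- ncol(beta)
    cd <- DataFrame(
        patient_id = rep_len(as.character(patientId), n),
        timepoint = rep_len(as.character(timepoint), n),
        sorted_flag = rep_len(as.logical(sortedFlag), n),
        group = rep_len(as.character(group), n),
        row.names = colnames(beta))
    se <- SummarizedExperiment(assays = list(beta = beta), colData = cd)
    new("BetaMatrix", se)
}

#' @rdname ReferencePanel
#' @export
setClass("ReferencePanel", representation(profiles = "matrix"))

setValidity("ReferencePanel", function(object) {
    msg <- character()
    p <- object@profiles
    if (!identical(sort(colnames(p)), sort(cellTypeNames())))
        msg <- c(msg, paste("profiles must have exactly the cell types:",
            paste(cellTypeNames(), collapse = ", ")))
    if (nrow(p) < 1)
        msg <- c(msg, "at least one marker CpG is required")
    if (is.null(rownames(p)))
        msg <- c(msg, "marker CpG ids are required as rownames")
    if (any(is.na(p)) || any(p < 0 | p > 1))
        msg <- c(msg, "reference beta values must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Cell-type reference methylation panel
#'
#' Mean beta values of marker CpGs in each of the five reference cell
#' types (B, NK, CD4+ T, CD8+ T, neutrophil).  Used as the design matrix
#' of the constrained least-squares deconvolution.
#'
#' @param profiles Numeric matrix, marker CpGs x 5 cell types, with
#'   rownames (CpG ids) and colnames matching [cellTypeNames()].
#'
#' @return A \code{ReferencePanel} object.
#' @export
#' @examples
#' p <- matrix(runif(10), 2, 5,
#'     dimnames = list(c("cg1", "cg2"), cellTypeNames()))
#' ReferencePanel(p)
ReferencePanel <- function(profiles) {
    profiles <- as.matrix(profiles)[, cellTypeNames(), drop = FALSE]
    new("ReferencePanel", profiles = profiles)
}

setMethod("show", "ReferencePanel", function(object) {
    cat("ReferencePanel:", nrow(object@profiles), "marker CpGs x",
        ncol(object@profiles), "cell types (",
        paste(colnames(object@profiles), collapse = ", "), ")\n")
    invisible(NULL)
})

#' @rdname CompositionEstimate
#' @export
setClass("CompositionEstimate", representation(proportions = "matrix"))

setValidity("CompositionEstimate", function(object) {
    p <- object@proportions
    msg <- character()
    if (!identical(colnames(p), cellTypeNames()))
        msg <- c(msg, "columns must be the five cell types, in order")
    if (any(p < -1e-8))
        msg <- c(msg, "proportions must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
        msg <- c(msg, "each sample's proportions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Estimated cell-type composition of samples
#'
#' Per-sample mixing proportions of the five reference cell types, on the
#' unit simplex (non-negative, summing to one).
#'
#' @param proportions Numeric matrix, samples x 5 cell types; rownames are
#'   sample ids.
#'
#' @return A \code{CompositionEstimate} object.
#' @export
#' @examples
#' w <- matrix(rep(0.2, 5), 1, dimnames = list("S1", cellTypeNames()))
#' CompositionEstimate(w)
CompositionEstimate <- function(proportions) {
    proportions <- as.matrix(proportions)[, cellTypeNames(), drop = FALSE]
    new("CompositionEstimate", proportions = proportions)
}

setMethod("show", "CompositionEstimate", function(object) {
    cat("CompositionEstimate for", nrow(object@proportions), "samples\n")
    print(head(round(object@proportions, 4)))
    if (nrow(object@proportions) > 6) cat("...\n")
    invisible(NULL)
})
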