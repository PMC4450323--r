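## Readers and writers for the pipeline's tabular interchange formats.
## Allele counts, beta matrices (with a metadata sidecar), reference
## panels and manifests travel as TSV; peaks as BED (via rtracklayer);
## gene sets as GMT (via fgsea); dendrograms as Newick (via ape).

.checkCols <- function(df, need, path) {
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("file ", path, " lacks columns: ",
            paste(missing, collapse = ", "))
    invisible(df)
}

#' Read and write tri-sample allele counts
#'
#' TSV with columns \code{site_id}, \code{patient_id}, \code{chrom},
#' \code{pos} (1-based) and the six ref/alt count columns for germline
#' and the two tumor time points.
#'
#' @param path File path.
#' @param x A [TriSampleCounts()] object.
#' @return \code{readAlleleCounts} returns a \code{TriSampleCounts};
#'   \code{writeAlleleCounts} returns \code{path} invisibly.
#' @export
readAlleleCounts <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .checkCols(df, .triSampleCols, path)
    TriSampleCounts(df)
}

#' @rdname readAlleleCounts
#' @export
writeAlleleCounts <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read and write beta matrices with a metadata sidecar
#'
#' The matrix TSV has CpG ids in the first column and one column per
#' sample; the sidecar TSV has columns \code{sample_id},
#' \code{patient_id}, \code{timepoint} and optionally
#' \code{sorted_flag}, \code{group}, \code{pct_cd5cd19}.
#'
#' @param path,metaPath Paths to the matrix and sidecar TSVs.
#' @param x A [BetaMatrix()].
#' @return \code{readBetaMatrix} returns a \code{BetaMatrix};
#'   \code{writeBetaMatrix} returns \code{path} invisibly.
#' @export
readBetaMatrix <- function(path, metaPath) {
    m <- read.delim(path, row.names = 1, check.names = FALSE)
    meta <- read.delim(metaPath, stringsAsFactors = FALSE)
    .checkCols(meta, c("sample_id", "patient_id", "timepoint"), metaPath)
    missing <- setdiff(colnames(m), meta$sample_id)
    if (length(missing))
        stop("samples without metadata: ",
            paste(missing, collapse = ", "))
    meta <- meta[match(colnames(m), meta$sample_id), ]
    bm <- BetaMatrix(as.matrix(m), patientId = meta$patient_id,
        timepoint = meta$timepoint,
        sortedFlag = meta$sorted_flag %||% FALSE,
        group = meta$group %||% NA_character_)
    # optional extra metadata (e.g. pct_cd5cd19) rides along in colData
    extra <- setdiff(colnames(meta), c("sample_id", "patient_id",
        "timepoint", "sorted_flag", "group"))
    for (cc in extra) colData(bm)[[cc]] <- meta[[cc]]
    bm
}

#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(x, path, metaPath) {
    m <- betaValues(x)
    write.table(data.frame(cpg_id = rownames(m), m, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(colData(x))
    write.table(data.frame(sample_id = rownames(cd), cd,
        check.names = FALSE), metaPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read externally estimated subclone cluster counts
#'
#' TSV with columns \code{patient_id} and \code{n_clusters}, as produced
#' by external subclonal-architecture tools; the counts are imported,
#' not computed here.
#'
#' @param path File path.
#' @return A \code{data.frame}.
#' @export
readClusterCounts <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .checkCols(df, c("patient_id", "n_clusters"), path)
    if (any(df$n_clusters < 1 | df$n_clusters != round(df$n_clusters)))
        stop("n_clusters must be positive integers")
    df
}

#' Read a cell-type reference panel from TSV
#'
#' TSV with a \code{cpg_id} column and one column per cell type
#' (\code{B}, \code{NK}, \code{CD4T}, \code{CD8T}, \code{Neutrophil}).
#'
#' @param path File path.
#' @return A [ReferencePanel()].
#' @export
readReferencePanel <- function(path) {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    ReferencePanel(as.matrix(df))
}

#' @rdname readReferencePanel
#' @export
writeReferencePanel <- function(x, path) {
    m <- profileMatrix(x)
    write.table(data.frame(cpg_id = rownames(m), m, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read copy-number segment calls
#'
#' BED-like TSV: \code{patient_id}, \code{chrom}, \code{start},
#' \code{end} (0-based half-open), \code{copy_number},
#' \code{confidence}, \code{timepoint}.
#'
#' @param path File path.
#' @return A \code{data.frame}.
#' @export
readCNASegments <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .checkCols(df, c("patient_id", "chrom", "start", "end", "timepoint"),
        path)
    df
}

#' Read ChIP-seq peaks from BED
#'
#' BED3+ (0-based half-open), parsed with
#' \code{rtracklayer::import}.
#'
#' @param path File path.
#' @return A [GenomicRanges::GRanges].
#' @export
readPeakBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' Read a CpG manifest
#'
#' TSV with columns \code{cpg_id}, \code{chrom}, \code{pos} (1-based)
#' and \code{gene_symbols} (semicolon-joined).
#'
#' @param path File path.
#' @return A \code{data.frame}.
#' @export
readManifest <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    .checkCols(df, c("cpg_id", "chrom", "pos", "gene_symbols"), path)
    df
}

#' Read gene sets from GMT
#'
#' Standard GMT (set name, description, tab-separated members), parsed
#' with \code{fgsea::gmtPathways}.
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
readGMT <- function(path) {
    fgsea::gmtPathways(path)
}

#' Read a one-per-line identifier list
#'
#' @param path File path.
#' @return A character vector.
#' @export
readIdList <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    x[nzchar(x)]
}

#' Write a dendrogram in Newick format
#'
#' @param tree An [ape::phylo] (e.g. from [similarityClustering()]).
#' @param path File path.
#' @return \code{path} invisibly.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

.writeTSV <- function(df, path) {
    write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
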