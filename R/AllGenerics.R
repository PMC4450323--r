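#' Accessors for ProgressionKit containers
#'
#' \code{betaValues} returns the beta assay of a [BetaMatrix()];
#' \code{sampleInfo} its column metadata.  \code{markerIds},
#' \code{cellTypes} and \code{profileMatrix} access a [ReferencePanel()];
#' \code{proportions} the matrix inside a [CompositionEstimate()].
#'
#' @param x An object of the documented class.
#' @return The extracted component.
#' @name accessors
#' @examples
#' p <- matrix(runif(10), 2, 5,
#'     dimnames = list(c("cg1", "cg2"), cellTypeNames()))
#' panel <- ReferencePanel(p)
#' cellTypes(panel)
#' markerIds(panel)
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setMethod("betaValues", "BetaMatrix", function(x) assay(x, "beta"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setMethod("sampleInfo", "BetaMatrix", function(x) colData(x))

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname accessors
#' @export
setMethod("markerIds", "ReferencePanel",
    function(x) rownames(x@profiles))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setMethod("cellTypes", "ReferencePanel",
    function(x) colnames(x@profiles))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setMethod("profileMatrix", "ReferencePanel", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setMethod("proportions", "CompositionEstimate",
    function(x) x@proportions)

#' @rdname deconvolve
#' @export
setGeneric("deconvolve",
    function(x, panel, ...) standardGeneric("deconvolve"))

#' Expected variant allele fractions under a clone structure
#'
#' For each variant of a [CloneStructure()], the expected alternate
#' allele fraction at each time point is \code{purity * prevalence / 2}
#' for a heterozygous variant in a diploid genome, where prevalence is
#' the summed cellular fraction of the clones carrying the variant (1 for
#' trunk variants).
#'
#' @param object A \code{CloneStructure}.
#' @return A two-column matrix (\code{t1}, \code{t2}) with one row per
#'   variant.
#' @export
#' @examples
#' cs <- CloneStructure("P1", c(1, 0), c(1, 0), c(1L, 2L), purityT1 = 0.8,
#'     purityT2 = 0.8)
#' expectedVAF(cs)  # clone carried by all tumor cells at purity 0.8 -> 0.4
setGeneric("expectedVAF", function(object) standardGeneric("expectedVAF"))

#' @rdname expectedVAF
#' @export
setMethod("expectedVAF", "CloneStructure", function(object) {
    prev <- function(fr) {
        if (object@nesting == "linear")
            cumprev <- rev(cumsum(rev(fr)))
        else cumprev <- fr
        c(1, cumprev)[object@variantClone + 1L]
    }
    cbind(t1 = object@purityT1 * prev(object@fractionsT1) / 2,
          t2 = object@purityT2 * prev(object@fractionsT2) / 2)
})
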