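## Reference-based cell-type deconvolution and composition adjustment.
##
## A bulk sample's marker-CpG beta vector is modelled as a mixture of the
## five reference profiles: beta ~ R w with w on the unit simplex.  The
## constrained least-squares problem min ||R w - beta||^2 s.t. w >= 0,
## sum(w) = 1 is solved exactly by enumerating active sets: for each of
## the 31 non-empty supports the equality-constrained solution is
## computed in closed form (Lagrange system), and the feasible candidate
## with the smallest residual is the global optimum (the optimal active
## set is always among them, and singleton supports guarantee at least
## one feasible candidate).

.simplexLS <- function(R, b) {
    k <- ncol(R)
    best <- NULL
    bestObj <- Inf
    for (mask in seq_len(2^k - 1)) {
        S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
        Rs <- R[, S, drop = FALSE]
        A <- rbind(cbind(2 * crossprod(Rs), rep(1, length(S))),
                   c(rep(1, length(S)), 0))
        rhs <- c(2 * crossprod(Rs, b), 1)
        sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        w <- sol[seq_along(S)]
        if (any(w < -1e-9)) next
        w <- pmax(w, 0)
        w <- w / sum(w)
        obj <- sum((Rs %*% w - b)^2)
        if (obj < bestObj - 1e-12) {
            bestObj <- obj
            best <- numeric(k)
            best[S] <- w
        }
    }
    best
}

#' Estimate cell-type composition by constrained least squares
#'
#' Deconvolutes bulk methylation profiles into proportions of the five
#' reference cell types using the cell-type-specific marker CpGs of a
#' [ReferencePanel()]: solves \code{min ||R w - beta||^2} subject to
#' \code{w >= 0} and \code{sum(w) = 1}, per sample.
#'
#' @param x A named numeric vector of beta values covering all marker
#'   CpGs, or a [BetaMatrix()] whose rows include them.
#' @param panel A \code{ReferencePanel}.
#' @param ... Unused.
#'
#' @return A [CompositionEstimate()].
#' @export
#' @examples
#' p <- rbind(diag(5) * 0.6 + 0.2)
#' dimnames(p) <- list(paste0("cg", 1:5), cellTypeNames())
#' panel <- ReferencePanel(p)
#' beta <- p[, "B"]                       # a pure B-cell sample
#' proportions(deconvolve(beta, panel))   # (1, 0, 0, 0, 0)
setMethod("deconvolve", "numeric", function(x, panel, ...) {
    stopifnot(is(panel, "ReferencePanel"))
    R <- profileMatrix(panel)
    missing <- setdiff(rownames(R), names(x))
    if (length(missing))
        stop("beta vector lacks marker CpGs: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")
    if (qr(R)$rank < ncol(R))
        stop("reference profile matrix is rank deficient; cell types ",
            "are not distinguishable from these markers")
    w <- .simplexLS(R, x[rownames(R)])
    m <- matrix(w, nrow = 1, dimnames = list("sample", colnames(R)))
    CompositionEstimate(m)
})

#' @rdname deconvolve
#' @export
setMethod("deconvolve", "BetaMatrix", function(x, panel, ...) {
    R <- profileMatrix(panel)
    missing <- setdiff(rownames(R), rownames(x))
    if (length(missing))
        stop("BetaMatrix lacks marker CpGs: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")
    if (qr(R)$rank < ncol(R))
        stop("reference profile matrix is rank deficient")
    b <- betaValues(x)[rownames(R), , drop = FALSE]
    W <- t(vapply(seq_len(ncol(b)), function(j) .simplexLS(R, b[, j]),
        numeric(ncol(R))))
    dimnames(W) <- list(colnames(b), colnames(R))
    CompositionEstimate(W)
})

#' Adjust beta values for cellular composition
#'
#' Removes composition-driven variation: per CpG, ordinary least squares
#' of beta on the cell-type proportions across all samples (intercept
#' plus four of the five proportions -- the neutrophil column is dropped
#' because the simplex constraint makes the five columns collinear); the
#' adjusted value is the CpG's grand mean plus the residual, clamped to
#' \code{[0,1]}.  Identical compositions across samples leave the matrix
#' unchanged, and the operation is idempotent.
#'
#' @param betas A [BetaMatrix()].
#' @param comps A [CompositionEstimate()] with one row per sample of
#'   \code{betas} (matched by rowname when available).
#'
#' @return A \code{BetaMatrix} of adjusted values with the same
#'   dimensions and metadata.
#' @export
adjustForComposition <- function(betas, comps) {
    stopifnot(is(betas, "BetaMatrix"), is(comps, "CompositionEstimate"))
    W <- proportions(comps)
    if (nrow(W) != ncol(betas))
        stop("need one composition per sample (got ", nrow(W), " for ",
            ncol(betas), " samples)")
    if (!is.null(rownames(W)) && !is.null(colnames(betas)) &&
        all(colnames(betas) %in% rownames(W)))
        W <- W[colnames(betas), , drop = FALSE]
    X <- cbind(1, W[, setdiff(colnames(W), "Neutrophil"), drop = FALSE])
    if (nrow(X) < ncol(X))
        stop("fewer samples than regression coefficients")
    B <- betaValues(betas)
    qrX <- qr(X)
    resid <- t(qr.resid(qrX, t(B)))
    adj <- pmin(pmax(rowMeans(B) + resid, 0), 1)
    out <- betas
    assay(out, "beta") <- adj
    out
}

#' Change in B-cell methylation load between time points
#'
#' Mean signed beta change over B-cell-specific marker CpGs, oriented so
#' that an increasing B-cell (leukemia) load increases the score.  At
#' B-cell markers where the B-cell reference is hypomethylated relative
#' to the other cell types, a rising B-cell fraction lowers beta, so that
#' marker's change enters with a negative sign; hypermethylated markers
#' enter positively.
#'
#' @param betasT1,betasT2 Named beta vectors for one patient's two
#'   samples (unadjusted values: the score measures composition itself).
#' @param bCellSites CpG ids of B-cell-specific markers.
#' @param orientation Named vector of \code{+1}/\code{-1} per site
#'   (positive = methylation rises with B-cell load).  Default all
#'   \code{+1}.
#'
#' @return The signed score (a single number; 0 for identical vectors).
#' @export
#' @examples
#' b1 <- c(cg1 = 0.5, cg2 = 0.4)
#' bCellScore(b1, b1 + 0.1, c("cg1", "cg2"))   # 0.1
bCellScore <- function(betasT1, betasT2, bCellSites, orientation = NULL) {
    if (length(bCellSites) == 0)
        stop("empty B-cell site set")
    missing <- setdiff(bCellSites, intersect(names(betasT1),
        names(betasT2)))
    if (length(missing))
        stop("sites absent from the beta vectors: ",
            paste(head(missing, 5), collapse = ", "))
    if (is.null(orientation))
        orientation <- setNames(rep(1, length(bCellSites)), bCellSites)
    mean(orientation[bCellSites] *
        (betasT2[bCellSites] - betasT1[bCellSites]))
}
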