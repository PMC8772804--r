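#' @import methods
NULL

#' AbundanceTable: samples-by-taxa abundance matrix
#'
#' Central container of the package. Samples are rows and taxa are columns
#' regardless of the orientation of the input file; a taxonomy map
#' (species -> genus) travels with the table so that genus-level collapsing
#' and enterotype labelling need no external lookups.
#'
#' Validity rules: no negative entries; when \code{relative} is \code{TRUE}
#' each row sums to 1 within 1e-9 (all-zero rows are forbidden); when a
#' rarefaction \code{depth} is recorded every row sums to exactly that depth.
#'
#' @slot counts numeric matrix, samples x taxa, with dimnames.
#' @slot taxonomy named character vector mapping species id to genus
#'   (may be empty, e.g. for genus-level tables).
#' @slot rank character, taxonomic rank of the columns ("species", "genus").
#' @slot relative logical, whether rows are relative abundances.
#' @slot depth numeric, rarefaction depth or \code{NA_real_}.
#'
#' @aliases AbundanceTable
#' @exportClass AbundanceTable
setClass("AbundanceTable",
         representation(counts = "matrix",
                        taxonomy = "character",
                        rank = "character",
                        relative = "logical",
                        depth = "numeric"),
         prototype(taxonomy = character(), rank = "species",
                   relative = FALSE, depth = NA_real_))

setValidity("AbundanceTable", function(object) {
    x <- object@counts
    if (!is.numeric(x)) return("counts must be a numeric matrix")
    if ((nrow(x) > 0 && is.null(rownames(x))) ||
        (ncol(x) > 0 && is.null(colnames(x))))
        return("counts must carry sample (row) and taxon (column) names")
    if (anyNA(x)) return("counts must not contain NA")
    if (any(x < 0)) return("negative abundance entries are not allowed")
    if (object@relative) {
        rs <- rowSums(x)
        if (any(rs == 0)) return("relative table contains an all-zero row")
        if (any(abs(rs - 1) > 1e-9))
            return("relative abundances must sum to 1 per sample (tol 1e-9)")
    }
    if (!is.na(object@depth)) {
        if (object@relative) return("a rarefied table cannot be relative")
        if (any(rowSums(x) != object@depth))
            return(sprintf("rarefied rows must sum to exactly %g", object@depth))
    }
    if (!object@rank %in% c("species", "genus", "KO", "module"))
        return("rank must be one of species/genus/KO/module")
    TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts numeric matrix (samples x taxa). A vector of taxon names is
#'   required through \code{colnames}; unnamed samples get \code{S1..Sn}.
#' @param taxonomy named character vector, species id -> genus.
#' @param rank rank of the columns.
#' @param relative logical flag for relative abundances.
#' @param depth rarefaction depth if the table is rarefied.
#' @return an \linkS4class{AbundanceTable}.
#' @examples
#' m <- matrix(c(5, 3, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' abundanceTable(m)
#' @export
abundanceTable <- function(counts, taxonomy = character(), rank = "species",
                           relative = FALSE, depth = NA_real_) {
    counts <- as.matrix(counts)
    rn <- rownames(counts)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(counts)))
    if (nrow(counts) && is.null(rownames(counts)))
        rn <- paste0("S", seq_len(nrow(counts)))
    cn <- colnames(counts)
    if (is.null(cn) && ncol(counts) == 0) cn <- character(0)
    dimnames(counts) <- list(rn, cn)
    new("AbundanceTable", counts = counts, taxonomy = taxonomy, rank = rank,
        relative = relative, depth = as.numeric(depth))
}

#' DMMFit: a fitted Dirichlet multinomial mixture
#'
#' Holds the estimates of one expectation-maximisation fit: mixture weights,
#' per-component Dirichlet parameters, per-sample responsibilities, the final
#' log-likelihood and its trace across iterations, and the two model-order
#' scores (Laplace-approximate log-evidence with a BIC fallback).
#'
#' @slot K integer, number of components.
#' @slot weights numeric length-K mixture weights (sum 1).
#' @slot alpha K x J matrix of positive Dirichlet parameters.
#' @slot responsibilities N x K matrix, rows sum to 1.
#' @slot logLik final observed-data log-likelihood.
#' @slot llTrace log-likelihood at each EM iteration (non-decreasing).
#' @slot evidence Laplace-approximate log model evidence under a vague
#'   exponential prior on the Dirichlet parameters; when the Hessian blocks
#'   are unusable (\code{laplaceOK} FALSE) it holds the BIC-style
#'   unit-information surrogate on the same scale.
#' @slot laplaceOK logical, whether the Laplace Hessian blocks were usable.
#' @slot bic log-evidence-scale BIC, logLik - d/2 log N (reporting only).
#' @slot converged logical convergence flag.
#' @slot iterations integer EM iterations of the winning restart.
#' @slot nRestarts restarts attempted.
#' @slot seed seed the fit consumed.
#'
#' @aliases DMMFit
#' @exportClass DMMFit
setClass("DMMFit",
         representation(K = "integer", weights = "numeric", alpha = "matrix",
                        responsibilities = "matrix", logLik = "numeric",
                        llTrace = "numeric", evidence = "numeric",
                        laplaceOK = "logical",
                        bic = "numeric", converged = "logical",
                        iterations = "integer", nRestarts = "integer",
                        seed = "integer"))

setValidity("DMMFit", function(object) {
    if (abs(sum(object@weights) - 1) > 1e-8)
        return("mixture weights must sum to 1")
    if (any(object@alpha <= 0)) return("Dirichlet parameters must be positive")
    if (nrow(object@responsibilities) > 0 &&
        any(abs(rowSums(object@responsibilities) - 1) > 1e-8))
        return("responsibility rows must sum to 1")
    TRUE
})
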