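#' Accessors for AbundanceTable
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @return \code{abundances} the numeric matrix (samples x taxa);
#'   \code{sampleIDs}/\code{taxonIDs} the dimnames; \code{taxonomyMap} the
#'   species -> genus map; \code{taxonRank} the column rank; \code{isRelative}
#'   and \code{rarefiedDepth} the normalisation state.
#' @examples
#' m <- matrix(c(5, 3, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' at <- abundanceTable(m)
#' abundances(at)
#' sampleIDs(at)
#' @name AbundanceTable-accessors
#' @aliases abundances sampleIDs taxonIDs taxonomyMap taxonRank isRelative
#'   rarefiedDepth
NULL

#' @rdname AbundanceTable-accessors
#' @export
setMethod("abundances", "AbundanceTable", function(x) x@counts)

#' @rdname AbundanceTable-accessors
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) rownames(x@counts))

#' @rdname AbundanceTable-accessors
#' @export
setMethod("taxonIDs", "AbundanceTable", function(x) colnames(x@counts))

#' @rdname AbundanceTable-accessors
#' @export
setMethod("taxonomyMap", "AbundanceTable", function(x) x@taxonomy)

#' @rdname AbundanceTable-accessors
#' @export
setMethod("taxonRank", "AbundanceTable", function(x) x@rank)

#' @rdname AbundanceTable-accessors
#' @export
setMethod("isRelative", "AbundanceTable", function(x) x@relative)

#' @rdname AbundanceTable-accessors
#' @export
setMethod("rarefiedDepth", "AbundanceTable", function(x) x@depth)

#' @export
setMethod("dim", "AbundanceTable", function(x) dim(x@counts))

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable: %d samples x %d %s-level taxa\n",
                nrow(object@counts), ncol(object@counts), object@rank))
    if (object@relative) cat("  relative abundances\n")
    if (!is.na(object@depth))
        cat(sprintf("  rarefied to %g reads per sample\n", object@depth))
    if (length(object@taxonomy))
        cat(sprintf("  taxonomy map: %d species -> %d genera\n",
                    length(object@taxonomy),
                    length(unique(object@taxonomy))))
})

#' Convert counts to relative abundances
#'
#' @param x an \linkS4class{AbundanceTable} with count data.
#' @return an \linkS4class{AbundanceTable} whose rows sum to 1.
#' @examples
#' m <- matrix(c(5, 3, 5, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' abundances(relativeAbundance(abundanceTable(m)))
#' @rdname relativeAbundance
#' @aliases relativeAbundance
#' @export
setMethod("relativeAbundance", "AbundanceTable", function(x) {
    rs <- rowSums(x@counts)
    if (any(rs == 0))
        stop("cannot normalise all-zero sample(s): ",
             paste(rownames(x@counts)[rs == 0], collapse = ", "))
    abundanceTable(x@counts / rs, taxonomy = x@taxonomy, rank = x@rank,
                   relative = TRUE)
})

#' Subset an AbundanceTable
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param i,j sample and taxon indices.
#' @param ... ignored.
#' @param drop ignored; the result is always an AbundanceTable.
#' @return an \linkS4class{AbundanceTable}. Normalisation flags are dropped
#'   when a taxon subset breaks them.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
    m <- x@counts[i, j, drop = FALSE]
    rel <- x@relative && ncol(m) == ncol(x@counts)
    dep <- if (ncol(m) == ncol(x@counts)) x@depth else NA_real_
    abundanceTable(m, taxonomy = x@taxonomy, rank = x@rank,
                   relative = rel, depth = dep)
})
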