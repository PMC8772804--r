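## ---------------------------------------------------------------------------
## taxprofile: per-read candidate assignments -> rarefied, filtered tables.
## The two-step filter mirrors a classifier + remapping-confirmation design:
## human-flagged reads are dropped, then reads failing either confirmation
## threshold (identity, aligned fraction) are removed as false positives.
## ---------------------------------------------------------------------------

.READ_COLS <- c("read_id", "sample_id", "candidate_taxon",
                "confirmed_identity", "aligned_fraction", "human_flag")

.checkReads <- function(reads) {
    miss <- setdiff(.READ_COLS, names(reads))
    if (length(miss))
        stop("read table lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (any(reads$confirmed_identity < 0 | reads$confirmed_identity > 1) ||
        any(reads$aligned_fraction < 0 | reads$aligned_fraction > 1))
        stop("confirmation statistics must lie in [0, 1]")
    invisible(reads)
}

#' Confirm per-read taxonomic assignments
#'
#' Applies the two-step false-positive filter: human-flagged reads are removed
#' unconditionally, then any read whose confirmation identity or aligned
#' fraction falls below its threshold is discarded. Retained rows are
#' unchanged, so the operation is idempotent.
#'
#' @param reads data.frame with columns \code{read_id, sample_id,
#'   candidate_taxon, confirmed_identity, aligned_fraction, human_flag}
#'   (one best-candidate row per read; multi-candidate tables must first be
#'   collapsed with \code{\link{collapseCandidates}}).
#' @param minIdentity minimum fraction of identical bases (default 0.80).
#' @param minAlignedFraction minimum aligned read fraction (default 0.50).
#' @return the filtered data.frame.
#' @examples
#' r <- data.frame(read_id = "r1", sample_id = "s1", candidate_taxon = "A",
#'                 confirmed_identity = 0.3, aligned_fraction = 0.9,
#'                 human_flag = FALSE)
#' nrow(confirmAssignments(r))  # 0: identity below threshold
#' @export
confirmAssignments <- function(reads, minIdentity = 0.80,
                               minAlignedFraction = 0.50) {
    if (minIdentity < 0 || minIdentity > 1 ||
        minAlignedFraction < 0 || minAlignedFraction > 1)
        stop("thresholds must lie in [0, 1]")
    if (nrow(reads) == 0) {
        warning("empty read table")
        return(reads)
    }
    .checkReads(reads)
    keep <- !reads$human_flag &
        reads$confirmed_identity >= minIdentity &
        reads$aligned_fraction >= minAlignedFraction
    reads[keep, , drop = FALSE]
}

#' Collapse multi-candidate reads to their best candidate
#'
#' When a classifier reports several candidate taxa per read, only the row
#' with the highest classifier score is kept; ties break towards the
#' lexicographically smallest taxon id, so the result is deterministic.
#'
#' @param reads data.frame with a \code{classifier_score} column and possibly
#'   several rows per \code{read_id}.
#' @return data.frame with one row per read.
#' @examples
#' r <- data.frame(read_id = c("r1", "r1"), sample_id = "s1",
#'                 candidate_taxon = c("B", "A"),
#'                 classifier_score = c(5, 5),
#'                 confirmed_identity = 0.9, aligned_fraction = 0.9,
#'                 human_flag = FALSE)
#' collapseCandidates(r)$candidate_taxon  # "A" wins the tie
#' @export
collapseCandidates <- function(reads) {
    o <- order(reads$read_id, -reads$classifier_score, reads$candidate_taxon)
    reads <- reads[o, , drop = FALSE]
    reads[!duplicated(reads$read_id), , drop = FALSE]
}

#' Tabulate confirmed reads into a species abundance table
#'
#' @param reads confirmed read table (see \code{\link{confirmAssignments}}).
#' @param taxonomy optional species -> genus map attached to the result.
#' @return an \linkS4class{AbundanceTable} of read counts, samples x species;
#'   the species universe is the union of observed candidate taxa.
#' @examples
#' r <- data.frame(read_id = paste0("r", 1:8), sample_id = "s1",
#'                 candidate_taxon = rep(c("A", "B"), c(5, 3)),
#'                 confirmed_identity = 0.9, aligned_fraction = 0.9,
#'                 human_flag = FALSE)
#' abundances(tabulateReads(r))
#' @export
tabulateReads <- function(reads, taxonomy = character()) {
    if (nrow(reads) == 0)
        return(abundanceTable(matrix(0L, 0, 0,
                                     dimnames = list(character(),
                                                     character())),
                              taxonomy = taxonomy))
    tab <- table(reads$sample_id, reads$candidate_taxon)
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    abundanceTable(m, taxonomy = taxonomy)
}

#' Rarefy an abundance table
#'
#' Subsamples every sample without replacement (multivariate hypergeometric)
#' to exactly \code{depth} reads. Samples with fewer than \code{depth} reads
#' are excluded and listed in the \code{"excluded"} attribute of the result
#' and in a message.
#'
#' @param x an \linkS4class{AbundanceTable} of integer counts.
#' @param depth target reads per sample (default 10000).
#' @param seed seed of the subsampling.
#' @return a rarefied \linkS4class{AbundanceTable} (every row sums to
#'   \code{depth}).
#' @examples
#' m <- matrix(c(300, 200, 60, 40), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' rowSums(abundances(rarefy(abundanceTable(m), depth = 50, seed = 1)))
#' @export
rarefy <- function(x, depth = 10000, seed = 1L) {
    stopifnot(is(x, "AbundanceTable"))
    if (depth < 1) stop("depth must be >= 1")
    m <- abundances(x)
    if (any(m != round(m))) stop("rarefaction requires integer counts")
    totals <- rowSums(m)
    keep <- totals >= depth
    if (!any(keep))
        stop("no sample reaches the rarefaction depth of ", depth,
             "; sample totals: ",
             paste(sprintf("%s=%d", rownames(m), as.integer(totals)),
                   collapse = ", "))
    excluded <- rownames(m)[!keep]
    if (length(excluded))
        message("rarefy: excluded ", length(excluded),
                " sample(s) below depth ", depth, ": ",
                paste(excluded, collapse = ", "))
    set.seed(seed)
    mk <- m[keep, , drop = FALSE]
    out <- matrix(0L, nrow(mk), ncol(mk), dimnames = dimnames(mk))
    J <- ncol(mk)
    for (i in seq_len(nrow(mk))) {
        if (totals[keep][i] == depth) {
            out[i, ] <- as.integer(mk[i, ])
        } else {
            pool <- rep.int(seq_len(J), mk[i, ])
            out[i, ] <- tabulate(sample(pool, depth), nbins = J)
        }
    }
    res <- abundanceTable(out, taxonomy = taxonomyMap(x), rank = taxonRank(x),
                          depth = depth)
    attr(res, "excluded") <- excluded
    res
}

#' Collapse a species table to a higher rank
#'
#' Counts are summed within genus; per-sample totals are conserved exactly.
#'
#' @param x an \linkS4class{AbundanceTable} at species level.
#' @param rank target rank (only \code{"genus"} is defined).
#' @param taxonomy species -> genus map; defaults to the map attached to
#'   \code{x}. Every species must be covered.
#' @return an \linkS4class{AbundanceTable} at genus level.
#' @examples
#' m <- matrix(c(4, 1, 6, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("g_sp1", "g_sp2")))
#' tax <- c(g_sp1 = "g", g_sp2 = "g")
#' abundances(collapseRank(abundanceTable(m, taxonomy = tax)))
#' @export
collapseRank <- function(x, rank = "genus", taxonomy = taxonomyMap(x)) {
    stopifnot(is(x, "AbundanceTable"), rank == "genus")
    if (taxonRank(x) == "genus") return(x)
    sp <- taxonIDs(x)
    orphans <- setdiff(sp, names(taxonomy))
    if (length(orphans))
        stop("species without a genus mapping: ",
             paste(orphans, collapse = ", "))
    g <- factor(taxonomy[sp])
    m <- abundances(x)
    ## sum columns within genus
    collapsed <- t(rowsum(t(m), group = g))
    colnames(collapsed) <- levels(g)
    abundanceTable(collapsed, rank = "genus", relative = isRelative(x),
                   depth = rarefiedDepth(x))
}

#' Prevalence/abundance feature filter
#'
#' Keeps feature j iff the fraction of samples in which its relative abundance
#' is at least \code{minAbund} reaches \code{minPrev}. Applied to relative
#' abundance tables before cross-sectional statistics.
#'
#' @param x a relative \linkS4class{AbundanceTable}.
#' @param minAbund relative-abundance threshold (default 5e-4).
#' @param minPrev minimum prevalence fraction (default 0.20).
#' @return the filtered table (relative flag dropped since rows no longer sum
#'   to 1); removed features are listed in the \code{"removed"} attribute.
#' @examples
#' m <- matrix(c(0.9, 0.999, 0.1, 0.001), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' filterFeatures(abundanceTable(m, relative = TRUE), minPrev = 1)
#' @export
filterFeatures <- function(x, minAbund = 5e-4, minPrev = 0.20) {
    stopifnot(is(x, "AbundanceTable"))
    if (!isRelative(x))
        stop("filterFeatures expects a relative abundance table")
    m <- abundances(x)
    prev <- colMeans(m >= minAbund)
    keep <- prev >= minPrev
    removed <- colnames(m)[!keep]
    res <- abundanceTable(m[, keep, drop = FALSE],
                          taxonomy = taxonomyMap(x), rank = taxonRank(x))
    attr(res, "removed") <- removed
    res
}
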