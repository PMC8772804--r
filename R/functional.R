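## ---------------------------------------------------------------------------
## functional_modules: KO abundance from species abundances x pan-genome
## presence, and gut-metabolic-module scoring from user-supplied definitions
## (median over step abundances, 2/3 step-coverage cutoff — the convention of
## the published gut metabolic module framework; both are configurable).
## ---------------------------------------------------------------------------

#' KO abundance from species abundances and pan-genome presence
#'
#' KO[s, k] = sum_j A[s, j] P[j, k]: the abundance of a gene family is the
#' summed abundance of the species whose pan-genome contains it. Species
#' absent from the presence matrix are excluded and listed in the
#' \code{"unmapped"} attribute.
#'
#' @param abundance \linkS4class{AbundanceTable} or matrix (samples x
#'   species), typically relative abundances.
#' @param presence binary species x KO matrix.
#' @return numeric matrix, samples x KOs, with the unmapped species recorded
#'   in an attribute.
#' @examples
#' A <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' P <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("spA", "spB"), c("K1", "K2")))
#' koAbundance(A, P)
#' @export
koAbundance <- function(abundance, presence) {
    A <- if (is(abundance, "AbundanceTable")) abundances(abundance) else
        as.matrix(abundance)
    P <- as.matrix(presence)
    if (!all(P %in% c(0, 1))) stop("presence matrix must be binary")
    unmapped <- setdiff(colnames(A), rownames(P))
    if (length(unmapped))
        message(length(unmapped), " species without pan-genome entry ",
                "excluded: ", paste(utils::head(unmapped, 5), collapse = ", "),
                if (length(unmapped) > 5) ", ..." else "")
    shared <- intersect(colnames(A), rownames(P))
    if (!length(shared)) stop("no species shared between abundance table ",
                              "and pan-genome matrix")
    ko <- A[, shared, drop = FALSE] %*% P[shared, , drop = FALSE]
    attr(ko, "unmapped") <- unmapped
    ko
}

#' Score metabolic modules from a KO abundance table
#'
#' For each module: the abundance of a step is the summed abundance of its
#' alternative KOs (duplicates within a step are counted once); module
#' coverage is the fraction of steps with positive abundance; the module
#' abundance is the median (or sum) over step abundances when coverage
#' reaches the cutoff, else 0. KOs referenced by a module but absent from
#' the table contribute zero and are logged.
#'
#' @param ko samples x KO matrix (see \code{\link{koAbundance}}).
#' @param modules list of module definitions: each a list with \code{id},
#'   \code{name}, \code{steps} (list of character KO vectors), as produced by
#'   \code{\link{readModuleDefinitions}} or \code{\link{generatePangenome}}.
#' @param coverageCutoff minimum step coverage (default 2/3).
#' @param aggregate "median" (default) or "sum" over step abundances.
#' @return list with \code{abundance} and \code{coverage} matrices
#'   (samples x modules).
#' @export
moduleAbundance <- function(ko, modules, coverageCutoff = 2 / 3,
                            aggregate = c("median", "sum")) {
    aggregate <- match.arg(aggregate)
    ko <- as.matrix(ko)
    ids <- vapply(modules, `[[`, character(1), "id")
    ab <- cov <- matrix(0, nrow(ko), length(modules),
                        dimnames = list(rownames(ko), ids))
    missingKOs <- character()
    for (mi in seq_along(modules)) {
        mod <- modules[[mi]]
        if (!length(mod$steps)) stop("module ", mod$id, " has zero steps")
        stepAb <- vapply(mod$steps, function(st) {
            st <- unique(st)
            missingKOs <<- union(missingKOs, setdiff(st, colnames(ko)))
            present <- intersect(st, colnames(ko))
            if (!length(present)) return(numeric(nrow(ko)))
            rowSums(ko[, present, drop = FALSE])
        }, numeric(nrow(ko)))
        stepAb <- matrix(stepAb, nrow(ko), length(mod$steps))
        cov[, mi] <- rowMeans(stepAb > 0)
        agg <- if (aggregate == "median") apply(stepAb, 1, stats::median)
        else rowSums(stepAb)
        ab[, mi] <- ifelse(cov[, mi] >= coverageCutoff, agg, 0)
    }
    if (length(missingKOs))
        message(length(missingKOs), " module KO(s) absent from the KO table ",
                "treated as zero")
    list(abundance = ab, coverage = cov)
}

#' Read module definitions
#'
#' Plain-text format: blank-line separated records, each starting with a
#' header line \code{MODULE<tab>id<tab>name} followed by one step per line as
#' comma-separated alternative KO ids.
#'
#' @param path file path.
#' @return list of module definitions (id, name, steps).
#' @export
readModuleDefinitions <- function(path) {
    lines <- trimws(readLines(path))
    modules <- list()
    cur <- NULL
    flush <- function(cur, modules) {
        if (!is.null(cur)) {
            if (!length(cur$steps))
                stop("module ", cur$id, " has zero steps")
            modules[[length(modules) + 1]] <- cur
        }
        modules
    }
    for (ln in lines) {
        if (ln == "") {
            modules <- flush(cur, modules)
            cur <- NULL
        } else if (startsWith(ln, "MODULE")) {
            modules <- flush(cur, modules)
            parts <- strsplit(ln, "\t")[[1]]
            if (length(parts) < 3)
                stop("malformed module header: ", ln)
            cur <- list(id = parts[2], name = parts[3], steps = list())
        } else {
            if (is.null(cur)) stop("step line before any MODULE header")
            kos <- trimws(strsplit(ln, ",")[[1]])
            kos <- kos[nzchar(kos)]
            if (!length(kos)) stop("empty step in module ", cur$id)
            cur$steps[[length(cur$steps) + 1]] <- kos
        }
    }
    flush(cur, modules)
}

#' Write module definitions
#'
#' @param modules list of module definitions (see
#'   \code{\link{readModuleDefinitions}}).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeModuleDefinitions <- function(modules, path) {
    lines <- unlist(lapply(modules, function(m) {
        c(paste("MODULE", m$id, m$name, sep = "\t"),
          vapply(m$steps, paste, character(1), collapse = ","), "")
    }))
    writeLines(lines, path)
    invisible(path)
}
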