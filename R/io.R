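## ---------------------------------------------------------------------------
## File I/O: abundance TSV (either orientation), clinical CSV, taxonomy TSV.
## ---------------------------------------------------------------------------

.readDelim <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
}

#' Read an abundance table
#'
#' @param path TSV/CSV file; first column holds the row identifiers.
#' @param orientation "taxa_rows" (taxa as rows, the common export layout) or
#'   "samples_rows". Tables are stored samples-as-rows internally either way.
#' @param taxonomy optional species -> genus map to attach.
#' @param rank rank of the taxa.
#' @return an \linkS4class{AbundanceTable}.
#' @export
readAbundanceTable <- function(path, orientation = c("taxa_rows",
                                                     "samples_rows"),
                               taxonomy = character(), rank = "species") {
    orientation <- match.arg(orientation)
    df <- .readDelim(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (!is.numeric(m)) stop("abundance file contains non-numeric entries")
    if (any(m < 0)) stop("abundance file contains negative counts")
    if (orientation == "taxa_rows") m <- t(m)
    abundanceTable(m, taxonomy = taxonomy, rank = rank)
}

#' Write an abundance table
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param path output file (TSV; taxa as rows).
#' @param orientation layout to write.
#' @return invisibly, the path.
#' @export
writeAbundanceTable <- function(x, path, orientation = c("taxa_rows",
                                                         "samples_rows")) {
    orientation <- match.arg(orientation)
    m <- abundances(x)
    if (orientation == "taxa_rows") m <- t(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.CLIN_REQUIRED <- c("subject_id", "visit")

#' Read a clinical table
#'
#' Validates the subject/visit schema, derives the 4-level obesity class from
#' BMI when absent, and checks that every V2 row has a V1 row.
#'
#' @param path CSV/TSV file with one row per subject x visit.
#' @return validated data.frame.
#' @export
readClinicalTable <- function(path) {
    df <- .readDelim(path)
    miss <- setdiff(.CLIN_REQUIRED, names(df))
    if (length(miss))
        stop("clinical table lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (!all(df$visit %in% c("V1", "V2")))
        stop("visit must be V1 or V2")
    if (anyDuplicated(df[, c("subject_id", "visit")]))
        stop("duplicate subject x visit rows")
    v2only <- setdiff(df$subject_id[df$visit == "V2"],
                      df$subject_id[df$visit == "V1"])
    if (length(v2only))
        stop("V2 rows without a V1 row: ", paste(v2only, collapse = ", "))
    if ("BMI" %in% names(df)) {
        oc <- obesityClass(df$BMI)
        if ("obesity_class" %in% names(df)) {
            bad <- which(as.character(df$obesity_class) != as.character(oc))
            if (length(bad))
                stop("obesity_class inconsistent with BMI in row(s): ",
                     paste(utils::head(bad, 5), collapse = ", "))
        } else df$obesity_class <- oc
    }
    for (v in c("SAS", "CPAP", "LMP"))
        if (v %in% names(df) && !is.logical(df[[v]]))
            df[[v]] <- as.logical(df[[v]])
    df
}

#' Read a taxonomy map
#'
#' @param path TSV with columns \code{species_id} and \code{genus}
#'   (a \code{species_name} column is allowed and ignored).
#' @return named character vector, species -> genus.
#' @export
readTaxonomy <- function(path) {
    df <- .readDelim(path)
    miss <- setdiff(c("species_id", "genus"), names(df))
    if (length(miss))
        stop("taxonomy file lacks required column(s): ",
             paste(miss, collapse = ", "))
    stats::setNames(as.character(df$genus), as.character(df$species_id))
}

#' Read abundance + clinical tables together
#'
#' Convenience loader that reports sample id mismatches between the two
#' tables.
#'
#' @param abundancePath,clinicalPath file paths.
#' @param taxonomyPath optional taxonomy TSV.
#' @param orientation abundance file orientation.
#' @return list with \code{abundance}, \code{clinical} and the ids found in
#'   only one of the tables.
#' @export
readTables <- function(abundancePath, clinicalPath, taxonomyPath = NULL,
                       orientation = "taxa_rows") {
    taxonomy <- if (!is.null(taxonomyPath)) readTaxonomy(taxonomyPath) else
        character()
    ab <- readAbundanceTable(abundancePath, orientation = orientation,
                             taxonomy = taxonomy)
    cl <- readClinicalTable(clinicalPath)
    clIds <- if ("sample_id" %in% names(cl)) cl$sample_id else
        paste0(cl$subject_id, "_", cl$visit)
    onlyAb <- setdiff(sampleIDs(ab), clIds)
    onlyCl <- setdiff(clIds, sampleIDs(ab))
    if (length(onlyAb) || length(onlyCl))
        message("sample id mismatch: ", length(onlyAb),
                " only in abundance, ", length(onlyCl), " only in clinical")
    list(abundance = ab, clinical = cl, onlyAbundance = onlyAb,
         onlyClinical = onlyCl)
}
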