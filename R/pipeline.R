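## ---------------------------------------------------------------------------
## Orchestration of the baseline (cross-sectional) and longitudinal
## (paired-visit) analyses. Every stage derives its own seed from the master
## seed and every artifact is stamped with the configuration hash.
## ---------------------------------------------------------------------------

.genusCounts <- function(rarefied) {
    if (taxonRank(rarefied) == "genus") rarefied else collapseRank(rarefied)
}

#' Run the baseline (cross-sectional) analysis
#'
#' Rarefies the species table, computes alpha diversity, collapses to genus
#' level, screens covariates by univariate dbRDA on the genus Bray-Curtis
#' matrix, enterotypes the cohort by DMM (model order selected over the
#' configured range unless \code{K} is fixed), labels the components, and
#' fits adjusted association models of richness (linear) and Bact2 status
#' (logistic) on the configured covariates.
#'
#' @param abundance species-level \linkS4class{AbundanceTable} of V1 samples.
#' @param clinical clinical data.frame (one row per sample; \code{sample_id}
#'   column or rownames matching the abundance table).
#' @param config an \code{\link{analysisConfig}}.
#' @param K optional fixed number of enterotypes (skips model selection).
#' @return list bundle: rarefied tables, diversity, ordination, dbRDA screen,
#'   enterotyping (model, labels, assignments), association tables, and
#'   provenance (config hash + seed, also stamped on the bundle).
#' @export
runBaselineAnalysis <- function(abundance, clinical,
                                config = analysisConfig(), K = NULL) {
    stopifnot(is(abundance, "AbundanceTable"))
    if (nrow(abundance) == 0 || ncol(abundance) == 0)
        stop("empty abundance table")
    if (nrow(abundance) < max(config$kRange))
        stop("fewer samples than the largest requested K (",
             max(config$kRange), ")")
    clinical <- as.data.frame(clinical)
    ids <- if ("sample_id" %in% names(clinical)) clinical$sample_id else
        rownames(clinical)
    shared <- intersect(sampleIDs(abundance), ids)
    if (!length(shared)) stop("no shared sample ids")
    abundance <- abundance[shared, ]
    clinical <- clinical[match(shared, ids), , drop = FALSE]

    rare <- rarefy(abundance, depth = config$rarefactionDepth,
                   seed = stageSeed(config$seed, "rarefy"))
    clinical <- clinical[match(sampleIDs(rare), shared), , drop = FALSE]
    diversity <- alphaDiversity(rare)
    genus <- .genusCounts(rare)
    genusRel <- relativeAbundance(genus)
    genusFilt <- filterFeatures(genusRel, config$featureMinAbundance,
                                config$featureMinPrevalence)
    d <- brayCurtis(genusRel)
    ord <- pcoa(d)

    dbrda <- do.call(rbind, lapply(
        intersect(config$dbrdaCovariates, names(clinical)), function(v) {
            if (length(unique(clinical[[v]])) < 2) return(NULL)
            r <- dbrdaUnivariate(d, clinical[[v]],
                                 nPerm = config$nPermutations,
                                 seed = stageSeed(config$seed,
                                                  paste0("dbrda_", v)))
            cbind(covariate = v, r)
        }))

    et <- enterotype(genus, K = K, kRange = config$kRange,
                     seed = stageSeed(config$seed, "enterotype"))
    asg <- et$assignments
    clinical$bact2 <- as.integer(asg$label[match(sampleIDs(rare),
                                                 asg$sample_id)] == "Bact2")
    clinical$richness <- diversity$richness[match(sampleIDs(rare),
                                                  diversity$sample_id)]

    testable <- setdiff(config$dbrdaCovariates, config$adjustment)
    richAssoc <- do.call(rbind, lapply(
        intersect(testable, names(clinical)), function(v)
            linearAssoc(clinical, "richness", v,
                        adjust = intersect(config$adjustment,
                                           names(clinical)),
                        standardize = TRUE)))
    bact2Assoc <- NULL
    if (length(unique(clinical$bact2)) == 2) {
        bact2Assoc <- do.call(rbind, lapply(
            c("richness", intersect(testable, names(clinical))), function(v)
                logisticAssoc(clinical, "bact2", v,
                              adjust = intersect(config$adjustment,
                                                 names(clinical)))))
        bact2Assoc$q <- bhAdjust(bact2Assoc$p)
    }
    if (!is.null(richAssoc)) richAssoc$q <- bhAdjust(richAssoc$p)

    enrich <- enterotypeFeatureEnrichment(abundances(genusFilt),
                                          asg$label)

    .stamp(list(rarefied = rare, diversity = diversity, genus = genus,
                genusFiltered = genusFilt, distance = d, ordination = ord,
                dbrda = dbrda, enterotypes = et,
                richnessAssociations = richAssoc,
                bact2Associations = bact2Assoc,
                enrichment = enrich,
                clinical = clinical,
                configHash = configHash(config), seed = config$seed),
           config)
}

#' Run the longitudinal (paired-visit) analysis
#'
#' Rarefies both visits, stratifies subjects by the baseline-cohort median
#' richness, compares richness fold-changes between strata, assigns both
#' visits to the baseline enterotype model and tests the transition tables
#' per stratum, fits per-feature linear mixed models of the visit effect with
#' subject (and LMP) random intercepts, summarises paired clinical changes,
#' runs a subject-stratified PERMANOVA of visit on the genus Bray-Curtis
#' matrix, and builds the propensity-matched LMP comparison.
#'
#' @param abundanceV1,abundanceV2 species-level \linkS4class{AbundanceTable}s;
#'   sample ids \code{<subject>_V1} / \code{<subject>_V2}.
#' @param clinical clinical data.frame with \code{subject_id}, \code{visit},
#'   \code{LMP} and covariates.
#' @param config an \code{\link{analysisConfig}}.
#' @param model optional fitted \linkS4class{DMMFit} from the baseline run;
#'   fitted on V1 genus counts when NULL.
#' @param K fixed K when fitting (default 4-range selection per config).
#' @return list bundle with strata, fold-change tests, transition tables,
#'   LMM results, paired clinical table, PERMANOVA and matching outputs.
#' @export
runLongitudinalAnalysis <- function(abundanceV1, abundanceV2, clinical,
                                    config = analysisConfig(), model = NULL,
                                    K = NULL) {
    subjV1 <- sub("_V1$", "", sampleIDs(abundanceV1))
    subjV2 <- sub("_V2$", "", sampleIDs(abundanceV2))
    paired <- intersect(subjV1, subjV2)
    if (length(paired) < 2)
        stop("need paired V1/V2 samples for >= 2 subjects")

    rare1 <- rarefy(abundanceV1, config$rarefactionDepth,
                    seed = stageSeed(config$seed, "rarefyV1"))
    rare2 <- rarefy(abundanceV2, config$rarefactionDepth,
                    seed = stageSeed(config$seed, "rarefyV2"))
    div1 <- alphaDiversity(rare1)
    div2 <- alphaDiversity(rare2)
    rich1 <- stats::setNames(div1$richness, sub("_V1$", "", div1$sample_id))
    rich2 <- stats::setNames(div2$richness, sub("_V2$", "", div2$sample_id))
    pairedOk <- intersect(names(rich1), names(rich2))

    ## median threshold over the full baseline cohort, applied to the pairs
    strata <- stratifyByMedian(rich1[pairedOk], reference = rich1)
    fold <- compareFoldChanges(rich1[pairedOk], rich2[pairedOk], strata)

    genus1 <- .genusCounts(rare1)
    genus2 <- .genusCounts(rare2)
    if (is.null(model)) {
        et <- enterotype(genus1, K = K, kRange = config$kRange,
                         seed = stageSeed(config$seed, "enterotype"))
        model <- et$model
        labels <- et$labels
    } else {
        labels <- labelComponents(model)
    }
    lab <- function(g) {
        a <- assignSamples(model, g)
        stats::setNames(unname(labels[a$component]),
                        sub("_V[12]$", "", a$sample_id))
    }
    lab1 <- lab(genus1); lab2 <- lab(genus2)
    common <- intersect(intersect(names(lab1), names(lab2)), pairedOk)
    transAll <- transitionTest(lab1[common], lab2[common])
    transStrata <- lapply(split(common, strata[common]), function(s)
        if (length(s) >= 2) transitionTest(lab1[s], lab2[s]) else NULL)

    ## visit PERMANOVA on combined genus profiles, subject-restricted perms
    both <- c(paste0(common, "_V1"), paste0(common, "_V2"))
    combined <- rbind(abundances(genus1)[paste0(common, "_V1"), ,
                                         drop = FALSE],
                      abundances(genus2)[paste0(common, "_V2"), ,
                                         drop = FALSE])
    dAll <- brayCurtis(abundanceTable(combined, rank = "genus"))
    visitVec <- rep(c("V1", "V2"), each = length(common))
    perma <- permanova(dAll, visitVec, strata = rep(common, 2),
                       nPerm = config$nPermutations,
                       seed = stageSeed(config$seed, "permanova"))

    ## per-feature LMMs on filtered relative species abundances
    relCombined <- combined / rowSums(combined)
    filt <- filterFeatures(abundanceTable(relCombined, rank = "genus",
                                          relative = TRUE),
                           config$featureMinAbundance,
                           config$featureMinPrevalence)
    clinical <- as.data.frame(clinical)
    lmpBySubj <- clinical$LMP[match(common,
                                    clinical$subject_id)]
    lmm <- lmmFeatures(abundances(filt), visit = visitVec,
                       subject = rep(common, 2),
                       lmp = if (!is.null(lmpBySubj)) rep(lmpBySubj, 2)
                       else NULL)

    pairedClin <- pairedClinical(clinical[clinical$subject_id %in% common, ])

    ## propensity-matched LMP comparison on baseline covariates
    base <- clinical[clinical$visit == "V1" &
                         clinical$subject_id %in% common, ]
    match <- NULL
    if ("LMP" %in% names(base) && length(unique(base$LMP)) == 2)
        match <- propensityMatch(base, treatment = "LMP",
                                 covariates = intersect(
                                     c("age", "sex", "weight"),
                                     names(base)),
                                 id = "subject_id")

    .stamp(list(strata = strata, foldChange = fold,
                transitionsAll = transAll, transitionsByStratum = transStrata,
                labelsV1 = lab1, labelsV2 = lab2, model = model,
                permanova = perma, lmm = lmm, pairedClinical = pairedClin,
                matching = match, diversityV1 = div1, diversityV2 = div2,
                configHash = configHash(config), seed = config$seed),
           config)
}
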