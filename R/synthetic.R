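## ---------------------------------------------------------------------------
## Synthetic cohort generator: the stated world every downstream stage is
## tested against. Defaults emulate a 263-subject weight-loss cohort with a
## 4-component Dirichlet-multinomial community structure (Bact1 / Bact2 /
## Rum / Bif), paired visits for 163/263 subjects, an LMP supplement arm of
## 188/263 at baseline, and Table-1-style covariate marginals.
## ---------------------------------------------------------------------------

.GENERA <- c("Bacteroides", "Faecalibacterium", "Bifidobacterium",
             "Prevotella", "Ruminococcus", "Blautia", "Roseburia",
             "Eubacterium", "Alistipes", "Akkermansia", "Parabacteroides",
             "Clostridium", "Coprococcus", "Dorea", "Streptococcus",
             "Lactobacillus", "Methanobrevibacter", "Dialister",
             "Oscillibacter", "Intestinimonas")

## genus-share archetypes (rows are normalised when the alpha matrix is built)
.GENUS_SHARES <- rbind(
    Bact1 = c(0.42, 0.08, 0.02, 0.010, 0.05, 0.05, 0.04, 0.05, 0.07, 0.020,
              0.06, 0.03, 0.03, 0.02, 0.01, 0.005, 0.005, 0.02, 0.02, 0.010),
    Bact2 = c(0.62, 0.03, 0.02, 0.005, 0.02, 0.04, 0.01, 0.03, 0.05, 0.005,
              0.07, 0.03, 0.01, 0.02, 0.02, 0.010, 0.002, 0.02, 0.01, 0.005),
    Rum   = c(0.12, 0.30, 0.03, 0.020, 0.10, 0.07, 0.07, 0.08, 0.04, 0.020,
              0.03, 0.04, 0.04, 0.03, 0.01, 0.005, 0.010, 0.02, 0.03, 0.020),
    Bif   = c(0.15, 0.08, 0.35, 0.010, 0.05, 0.06, 0.03, 0.05, 0.03, 0.010,
              0.03, 0.03, 0.03, 0.03, 0.03, 0.020, 0.003, 0.01, 0.01, 0.010))

## recognisable species names for taxa the weight-loss literature tracks
.NAMED_SPECIES <- c(Bacteroides = "Bacteroides_fragilis",
                    Faecalibacterium = "Faecalibacterium_prausnitzii",
                    Bifidobacterium = "Bifidobacterium_adolescentis",
                    Eubacterium = "Eubacterium_rectale",
                    Akkermansia = "Akkermansia_muciniphila",
                    Parabacteroides = "Parabacteroides_distasonis",
                    Methanobrevibacter = "Methanobrevibacter_smithii",
                    Streptococcus = "Streptococcus_thermophilus")

#' Default community archetypes
#'
#' Builds the species-level Dirichlet parameter matrix of the four default
#' enterotype archetypes. Each of 20 gut genera carries
#' \code{speciesPerGenus} species whose within-genus weights decay
#' geometrically; genus shares follow the canonical descriptions — Bact1/Bact2
#' Bacteroides-dominated with Bact2 at a much lower total concentration (low
#' richness and evenness), Rum dominated by Faecalibacterium at the highest
#' concentration, Bif enriched in Bifidobacterium.
#'
#' @param concentrations named numeric, total Dirichlet mass per component.
#' @param speciesPerGenus species per genus (default 8).
#' @return list with \code{alpha} (K x J species-level Dirichlet parameters),
#'   \code{taxonomy} (species -> genus map), \code{genera} and
#'   \code{components}.
#' @examples
#' a <- componentArchetypes()
#' dim(a$alpha)
#' @export
componentArchetypes <- function(concentrations = c(Bact1 = 120, Bact2 = 35,
                                                   Rum = 200, Bif = 100),
                                speciesPerGenus = 8) {
    stopifnot(all(concentrations > 0), speciesPerGenus >= 1)
    shares <- .GENUS_SHARES / rowSums(.GENUS_SHARES)
    colnames(shares) <- .GENERA
    w <- 0.6^(seq_len(speciesPerGenus) - 1)
    w <- w / sum(w)
    species <- unlist(lapply(.GENERA, function(g) {
        ids <- sprintf("%s_sp%02d", g, seq_len(speciesPerGenus))
        if (g %in% names(.NAMED_SPECIES)) ids[1] <- .NAMED_SPECIES[[g]]
        ids
    }))
    taxonomy <- stats::setNames(rep(.GENERA, each = speciesPerGenus), species)
    alpha <- matrix(0, nrow(shares), length(species),
                    dimnames = list(rownames(shares), species))
    for (k in rownames(shares))
        alpha[k, ] <- concentrations[[k]] *
            rep(shares[k, ], each = speciesPerGenus) * rep(w, length(.GENERA))
    list(alpha = alpha, taxonomy = taxonomy, genera = .GENERA,
         components = rownames(shares))
}

.T_LMP <- matrix(c(0.85, 0.02, 0.08, 0.05,   # from Bact1
                   0.44, 0.39, 0.09, 0.08,   # from Bact2: 44% exit to Bact1
                   0.25, 0.03, 0.67, 0.05,   # from Rum
                   0.25, 0.03, 0.07, 0.65),  # from Bif
                 4, 4, byrow = TRUE,
                 dimnames = list(c("Bact1", "Bact2", "Rum", "Bif"),
                                 c("Bact1", "Bact2", "Rum", "Bif")))
.T_NOLMP <- matrix(c(0.85, 0.05, 0.05, 0.05,
                     0.12, 0.80, 0.04, 0.04,
                     0.10, 0.06, 0.79, 0.05,
                     0.10, 0.06, 0.05, 0.79),
                   4, 4, byrow = TRUE, dimnames = dimnames(.T_LMP))

#' Generator configuration
#'
#' Assembles the parameters of \code{\link{generateCohort}}. Defaults encode
#' the stated cohort: N = 263 subjects, paired visits for a 163/263 fraction,
#' component weights with Bact2 at 19.4%, covariate marginals of the baseline
#' clinical table (age 50.6 (9.9) y, weight 90.5 (16.3) kg, 20.9% male, ...),
#' an LMP consumer share of 188/263, and LMP-specific enterotype transition
#' matrices in which Bact2 consumers predominantly exit towards Bact1.
#' Covariate-to-component planted logits default to zero (opt-in planting);
#' see the methods vignette.
#'
#' @param nSubjects cohort size.
#' @param fractionV2 fraction of subjects with a paired second visit.
#' @param piK mixture weights of the four archetypes (sum 1).
#' @param concentrations per-component total Dirichlet mass.
#' @param depthMean,depthDispersion negative-binomial sequencing depth model.
#' @param lmpFrac probability of LMP supplementation.
#' @param nCenters number of recruitment centres.
#' @param plantedLogits optional K x p matrix (rownames components, colnames
#'   clinical covariates) of per-unit log-odds added to the component logit
#'   after centring the covariate, e.g.
#'   \code{rbind(Bif = c(age = -0.02, sexF = 0.3))} expanded to K rows.
#' @param transitionLMP,transitionNoLMP K x K visit-transition matrices
#'   (rows sum to 1).
#' @param visitSpeciesLogFC named log fold-changes applied to the Dirichlet
#'   parameters of selected species at the second visit.
#' @param visitSumAlphaLogFC per-component log fold-change applied to the
#'   total concentration at the second visit, indexed by the visit-1
#'   component (default: Bact2 subjects gain +0.25, the planted
#'   low-diversity improvement).
#' @param falsePositiveRate,humanReadRate read-level generator rates.
#' @param identityTrue,identityFalse,alignedTrue,alignedFalse mean/sd pairs of
#'   the confirmation statistics for true and false assignments.
#' @param nKOs,presenceProb pan-genome generator parameters.
#' @param speciesPerGenus species per genus in the archetypes.
#' @param seed master seed.
#' @return a validated list of class \code{"EnteroShiftGeneratorConfig"}.
#' @examples
#' gc <- generatorConfig(nSubjects = 50, seed = 7)
#' @export
generatorConfig <- function(nSubjects = 263,
                            fractionV2 = 163 / 263,
                            piK = c(Bact1 = 0.300, Bact2 = 0.194,
                                    Rum = 0.300, Bif = 0.206),
                            concentrations = c(Bact1 = 120, Bact2 = 35,
                                               Rum = 200, Bif = 100),
                            depthMean = 25000, depthDispersion = 20,
                            lmpFrac = 188 / 263,
                            nCenters = 5,
                            plantedLogits = NULL,
                            transitionLMP = .T_LMP,
                            transitionNoLMP = .T_NOLMP,
                            visitSpeciesLogFC = c(
                                Akkermansia_muciniphila = 0.5,
                                Parabacteroides_distasonis = 0.3,
                                Methanobrevibacter_smithii = 0.3,
                                Eubacterium_rectale = -0.5,
                                Streptococcus_thermophilus = -0.3,
                                Bifidobacterium_adolescentis = -0.3),
                            visitSumAlphaLogFC = c(Bact1 = 0, Bact2 = 0.25,
                                                   Rum = 0, Bif = 0),
                            falsePositiveRate = 0.10,
                            humanReadRate = 0.005,
                            identityTrue = c(0.92, 0.03),
                            identityFalse = c(0.62, 0.10),
                            alignedTrue = c(0.90, 0.05),
                            alignedFalse = c(0.35, 0.15),
                            nKOs = 200, presenceProb = 0.3,
                            speciesPerGenus = 8,
                            seed = 1L) {
    if (abs(sum(piK) - 1) > 1e-8) stop("mixture weights piK must sum to 1")
    if (any(concentrations <= 0)) stop("concentrations must be positive")
    K <- length(piK)
    for (tm in list(transitionLMP, transitionNoLMP)) {
        if (!all(dim(tm) == c(K, K)))
            stop("transition matrix dimension must match the number of components")
        if (any(abs(rowSums(tm) - 1) > 1e-8))
            stop("transition matrix rows must sum to 1")
    }
    if (falsePositiveRate < 0 || falsePositiveRate > 1)
        stop("falsePositiveRate must lie in [0, 1]")
    cfg <- list(nSubjects = as.integer(nSubjects), fractionV2 = fractionV2,
                piK = piK, concentrations = concentrations,
                depthMean = depthMean, depthDispersion = depthDispersion,
                lmpFrac = lmpFrac, nCenters = as.integer(nCenters),
                plantedLogits = plantedLogits,
                transitionLMP = transitionLMP,
                transitionNoLMP = transitionNoLMP,
                visitSpeciesLogFC = visitSpeciesLogFC,
                visitSumAlphaLogFC = visitSumAlphaLogFC,
                falsePositiveRate = falsePositiveRate,
                humanReadRate = humanReadRate,
                identityTrue = identityTrue, identityFalse = identityFalse,
                alignedTrue = alignedTrue, alignedFalse = alignedFalse,
                nKOs = as.integer(nKOs), presenceProb = presenceProb,
                speciesPerGenus = speciesPerGenus,
                seed = as.integer(seed))
    class(cfg) <- "EnteroShiftGeneratorConfig"
    cfg
}

#' Draw one community composition
#'
#' One Dirichlet-multinomial draw: proportions from Dirichlet(alpha), then a
#' multinomial read allocation at the requested depth.
#'
#' @param alpha positive Dirichlet parameter vector (one component).
#' @param depth number of reads.
#' @param seed optional seed.
#' @return integer count vector of \code{length(alpha)} summing to
#'   \code{depth}, named like \code{alpha}.
#' @examples
#' sampleComposition(c(a = 10, b = 1, c = 1), depth = 100, seed = 1)
#' @export
sampleComposition <- function(alpha, depth, seed = NULL) {
    if (any(alpha <= 0)) stop("Dirichlet parameters must be strictly positive")
    if (depth < 1) stop("depth must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    p <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(p) == 0) p <- rep(1, length(alpha))  # guard against underflow
    x <- as.integer(stats::rmultinom(1, size = depth, prob = p / sum(p)))
    stats::setNames(x, names(alpha))
}

## vectorised Dirichlet-multinomial draws; alphaMat is n x J (one row per draw)
.drawCompositions <- function(alphaMat, depths) {
    n <- nrow(alphaMat); J <- ncol(alphaMat)
    g <- matrix(stats::rgamma(n * J, shape = alphaMat), n, J)
    g[g == 0] <- .Machine$double.xmin
    counts <- matrix(0L, n, J, dimnames = dimnames(alphaMat))
    for (i in seq_len(n))
        counts[i, ] <- as.integer(stats::rmultinom(1, depths[i],
                                                   g[i, ] / sum(g[i, ])))
    counts
}

.rnormTrunc <- function(n, mean, sd, lo = -Inf, hi = Inf)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

## Table-1 marginals: mean, sd, lower truncation
.CLIN_MARGINALS <- list(
    age = c(50.6, 9.9, 18), height = c(165.8, 7.9, 140),
    weight = c(90.5, 16.3, 50), waist = c(106.5, 12.4, 60),
    fat_mass = c(40.7, 4.7, 15), glycemia = c(1.02, 0.22, 0.4),
    insulinemia = c(14.9, 8.7, 1), HOMA_IR = c(4.1, 3.1, 0.2),
    HbA1c = c(5.8, 0.9, 3.5), total_cholesterol = c(5.5, 1.1, 2),
    triglycerides = c(1.6, 0.9, 0.3), HDL = c(1.4, 0.4, 0.4),
    LDL = c(3.4, 1.0, 0.8), ASAT = c(24.0, 10.0, 5),
    ALAT = c(30.2, 18.3, 5), GGT = c(41.0, 40.9, 5),
    creatinine = c(8.1, 1.5, 3), uricemia = c(52.1, 16.3, 15))

## Table-2 mean shifts at 10% weight loss (weight/BMI handled exactly)
.CLIN_V2_SHIFT <- c(waist = -10.6, fat_mass = -3.1, glycemia = -0.06,
                    insulinemia = -3.8, HOMA_IR = -1.8, HbA1c = -0.6,
                    total_cholesterol = -0.6, triglycerides = -0.5,
                    HDL = 0, LDL = -0.3, ASAT = -1.9, ALAT = -5.4,
                    GGT = -16, creatinine = -0.1, uricemia = -3.2)

#' Derive the 4-level obesity class from BMI
#'
#' Classes: BMI < 30 non-obesity; 30 <= BMI < 35 obesity; 35 <= BMI < 40
#' severe obesity; BMI >= 40 morbid obesity.
#'
#' @param bmi numeric vector (kg/m^2).
#' @return factor with the non-obesity class as reference level.
#' @examples
#' obesityClass(c(27, 33, 36, 41))
#' @export
obesityClass <- function(bmi) {
    cut(bmi, breaks = c(-Inf, 30, 35, 40, Inf), right = FALSE,
        labels = c("non-obesity", "obesity", "severe obesity",
                   "morbid obesity"))
}

#' Generate a synthetic paired-visit cohort
#'
#' Draws clinical covariates from the configured marginals, assigns each
#' subject a latent community component (multinomial logit over the mixture
#' weights plus any planted covariate logits), draws species-level
#' Dirichlet-multinomial counts per visit, applies LMP-stratum enterotype
#' transitions and planted per-species / per-concentration visit effects, and
#' records the full truth channel for tests.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{clinical} (one row per subject x visit),
#'   \code{abundanceV1}, \code{abundanceV2}
#'   (\linkS4class{AbundanceTable}s, species level), and \code{truth}
#'   (per-sample true components and the planted parameter values; never
#'   consumed by analysis code).
#' @examples
#' coh <- generateCohort(generatorConfig(nSubjects = 20, depthMean = 2000,
#'                                       seed = 1))
#' dim(coh$abundanceV1)
#' @export
generateCohort <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "EnteroShiftGeneratorConfig"))
    set.seed(stageSeed(config$seed, "cohort"))
    N <- config$nSubjects
    arch <- componentArchetypes(config$concentrations,
                                config$speciesPerGenus)
    K <- length(config$piK)
    comps <- names(config$piK)
    subjects <- sprintf("SUB%04d", seq_len(N))

    clin <- data.frame(subject_id = subjects, visit = "V1",
                       stringsAsFactors = FALSE)
    for (v in names(.CLIN_MARGINALS)) {
        m <- .CLIN_MARGINALS[[v]]
        clin[[v]] <- .rnormTrunc(N, m[1], m[2], lo = m[3])
    }
    clin$sex <- ifelse(stats::runif(N) < 0.209, "M", "F")
    clin$center <- sample(sprintf("C%02d", seq_len(config$nCenters)), N,
                          replace = TRUE)
    clin$BMI <- clin$weight / (clin$height / 100)^2
    clin$BSS <- pmin(7, pmax(1, round(stats::rnorm(N, 3.6, 1.3))))
    clin$SAS <- stats::runif(N) < 0.141
    clin$CPAP <- clin$SAS & stats::runif(N) < 0.67
    clin$LMP <- stats::runif(N) < config$lmpFrac
    clin$obesity_class <- obesityClass(clin$BMI)
    clin$sample_id <- paste0(subjects, "_V1")

    ## latent component: multinomial logit around log(piK)
    logits <- matrix(log(config$piK), N, K, byrow = TRUE,
                     dimnames = list(subjects, comps))
    if (!is.null(config$plantedLogits)) {
        pl <- config$plantedLogits
        for (k in rownames(pl)) for (v in colnames(pl)) {
            x <- if (v == "sexF") as.numeric(clin$sex == "F") else clin[[v]]
            logits[, k] <- logits[, k] + pl[k, v] * (x - mean(x))
        }
    }
    pr <- exp(logits - apply(logits, 1, max))
    pr <- pr / rowSums(pr)
    u <- stats::runif(N)
    compV1 <- comps[max.col(u < t(apply(pr, 1, cumsum)), "first")]

    depthsV1 <- stats::rnbinom(N, mu = config$depthMean,
                               size = config$depthDispersion)
    depthsV1 <- pmax(depthsV1, 500L)
    countsV1 <- .drawCompositions(arch$alpha[compV1, , drop = FALSE], depthsV1)
    rownames(countsV1) <- clin$sample_id
    abV1 <- abundanceTable(countsV1, taxonomy = arch$taxonomy)

    ## paired second visit
    nV2 <- round(config$fractionV2 * N)
    if (nV2 == 0) {
        rownames(clin) <- clin$sample_id
        return(list(clinical = clin, abundanceV1 = abV1, abundanceV2 = NULL,
                    truth = list(componentV1 = stats::setNames(compV1,
                                                               subjects),
                                 componentV2 = NULL, piK = config$piK,
                                 concentrations = config$concentrations,
                                 visitSpeciesLogFC = config$visitSpeciesLogFC,
                                 visitSumAlphaLogFC =
                                     config$visitSumAlphaLogFC,
                                 plantedLogits = config$plantedLogits)))
    }
    withV2 <- sort(sample(N, nV2))
    tmL <- config$transitionLMP; tmN <- config$transitionNoLMP
    compV2 <- character(nV2)
    for (ii in seq_len(nV2)) {
        i <- withV2[ii]
        tm <- if (clin$LMP[i]) tmL else tmN
        compV2[ii] <- sample(comps, 1, prob = tm[compV1[i], ])
    }
    alphaV2 <- arch$alpha[compV2, , drop = FALSE]
    fc <- config$visitSpeciesLogFC
    fc <- fc[names(fc) %in% colnames(alphaV2)]
    if (length(fc))
        alphaV2[, names(fc)] <- sweep(alphaV2[, names(fc), drop = FALSE], 2,
                                      exp(fc), `*`)
    alphaV2 <- alphaV2 * exp(config$visitSumAlphaLogFC[compV1[withV2]])
    depthsV2 <- pmax(stats::rnbinom(nV2, mu = config$depthMean,
                                    size = config$depthDispersion), 500L)
    countsV2 <- .drawCompositions(alphaV2, depthsV2)
    rownames(countsV2) <- paste0(subjects[withV2], "_V2")
    abV2 <- abundanceTable(countsV2, taxonomy = arch$taxonomy)

    clinV2 <- clin[withV2, ]
    clinV2$visit <- "V2"
    clinV2$sample_id <- rownames(countsV2)
    n2 <- nrow(clinV2)
    clinV2$weight <- 0.9 * clinV2$weight
    clinV2$BMI <- clinV2$weight / (clinV2$height / 100)^2
    for (v in names(.CLIN_V2_SHIFT)) {
        sdv <- .CLIN_MARGINALS[[v]][2]
        lo <- .CLIN_MARGINALS[[v]][3]
        clinV2[[v]] <- pmax(lo / 2, clinV2[[v]] + .CLIN_V2_SHIFT[[v]] +
                                stats::rnorm(n2, 0, 0.3 * sdv))
    }
    clinV2$obesity_class <- obesityClass(clinV2$BMI)
    clinical <- rbind(clin, clinV2)
    rownames(clinical) <- clinical$sample_id

    truth <- list(componentV1 = stats::setNames(compV1, subjects),
                  componentV2 = stats::setNames(compV2, subjects[withV2]),
                  piK = config$piK,
                  concentrations = config$concentrations,
                  visitSpeciesLogFC = config$visitSpeciesLogFC,
                  visitSumAlphaLogFC = config$visitSumAlphaLogFC,
                  plantedLogits = config$plantedLogits)
    list(clinical = clinical, abundanceV1 = abV1, abundanceV2 = abV2,
         truth = truth)
}

#' Generate a per-read candidate-assignment table
#'
#' A synthetic stand-in for a long-read classifier + remapping confirmation:
#' each read carries its best candidate taxon (the true taxon with probability
#' \code{1 - falsePositiveRate}, otherwise a random wrong taxon), a
#' classifier score, and two confirmation statistics (fraction of identical
#' bases, aligned fraction of the read) drawn from a high distribution for
#' true assignments and a low one for false ones. Human-contaminant reads are
#' appended at the configured rate and flagged.
#'
#' @param counts an \linkS4class{AbundanceTable} or count matrix
#'   (samples x taxa) giving the true community of each sample.
#' @param readsPerSample reads to draw per sample.
#' @param falsePositiveRate probability of a wrong candidate taxon.
#' @param seed seed.
#' @param identityTrue,identityFalse,alignedTrue,alignedFalse mean/sd pairs.
#' @param humanReadRate expected fraction of human-flagged extra reads.
#' @return list with \code{reads} (data.frame: read_id, sample_id,
#'   candidate_taxon, classifier_score, confirmed_identity, aligned_fraction,
#'   human_flag) and \code{truth} (true_taxon + false-positive flag per read).
#' @examples
#' m <- matrix(c(80, 20, 50, 50), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' ra <- generateReadAssignments(m, readsPerSample = 100,
#'                               falsePositiveRate = 0.1, seed = 1)
#' head(ra$reads)
#' @export
generateReadAssignments <- function(counts, readsPerSample,
                                    falsePositiveRate = 0.10, seed = 1L,
                                    identityTrue = c(0.92, 0.03),
                                    identityFalse = c(0.62, 0.10),
                                    alignedTrue = c(0.90, 0.05),
                                    alignedFalse = c(0.35, 0.15),
                                    humanReadRate = 0.005) {
    if (readsPerSample < 1) stop("readsPerSample must be >= 1")
    if (falsePositiveRate < 0 || falsePositiveRate > 1)
        stop("falsePositiveRate must lie in [0, 1]")
    if (is(counts, "AbundanceTable")) counts <- abundances(counts)
    set.seed(seed)
    taxa <- colnames(counts)
    out <- vector("list", nrow(counts))
    for (i in seq_len(nrow(counts))) {
        p <- counts[i, ]
        if (sum(p) == 0) next
        true <- sample(taxa, readsPerSample, replace = TRUE, prob = p)
        fp <- stats::runif(readsPerSample) < falsePositiveRate
        cand <- true
        if (any(fp))
            cand[fp] <- vapply(true[fp], function(tt)
                sample(setdiff(taxa, tt), 1), character(1))
        nh <- stats::rbinom(1, readsPerSample, humanReadRate)
        n <- readsPerSample + nh
        human <- c(rep(FALSE, readsPerSample), rep(TRUE, nh))
        cand <- c(cand, rep("Homo_sapiens", nh))
        true <- c(true, rep("Homo_sapiens", nh))
        fp <- c(fp, rep(FALSE, nh))
        idm <- ifelse(fp, identityFalse[1], identityTrue[1])
        ids <- ifelse(fp, identityFalse[2], identityTrue[2])
        alm <- ifelse(fp, alignedFalse[1], alignedTrue[1])
        als <- ifelse(fp, alignedFalse[2], alignedTrue[2])
        out[[i]] <- data.frame(
            read_id = sprintf("%s_r%06d", rownames(counts)[i], seq_len(n)),
            sample_id = rownames(counts)[i],
            candidate_taxon = cand,
            classifier_score = round(stats::rexp(n, 1 / 200)) + 1,
            confirmed_identity = .rnormTrunc(n, idm, ids, 0, 1),
            aligned_fraction = .rnormTrunc(n, alm, als, 0, 1),
            human_flag = human,
            stringsAsFactors = FALSE)
        out[[i]]$true_taxon <- true
        out[[i]]$false_positive <- fp
    }
    all <- do.call(rbind, out)
    truth <- all[, c("read_id", "true_taxon", "false_positive")]
    reads <- all[, c("read_id", "sample_id", "candidate_taxon",
                     "classifier_score", "confirmed_identity",
                     "aligned_fraction", "human_flag")]
    rownames(reads) <- rownames(truth) <- NULL
    list(reads = reads, truth = truth)
}

#' Generate a species pan-genome presence matrix and module fixture
#'
#' @param species character vector of species ids (or an integer count).
#' @param nKOs number of KEGG-ortholog-like gene families.
#' @param presenceProb Bernoulli probability that a species carries a KO.
#' @param seed seed.
#' @param nModules number of fixture metabolic modules (>= 3).
#' @return list with \code{presence} (binary species x KO matrix) and
#'   \code{modules} (list of module definitions: id, name, steps — each step a
#'   character vector of alternative KO ids; 1 to 4 steps per module).
#' @examples
#' pg <- generatePangenome(c("spA", "spB"), nKOs = 10, presenceProb = 0.5,
#'                         seed = 1)
#' pg$presence
#' @export
generatePangenome <- function(species, nKOs = 200, presenceProb = 0.3,
                              seed = 1L, nModules = 4) {
    if (presenceProb < 0 || presenceProb > 1)
        stop("presenceProb must lie in [0, 1]")
    if (is.numeric(species) && length(species) == 1)
        species <- sprintf("sp%03d", seq_len(species))
    if (length(species) < 1 || nKOs < 1) stop("dimensions must be >= 1")
    if (nModules < 3) stop("at least 3 fixture modules are required")
    set.seed(seed)
    kos <- sprintf("K%05d", seq_len(nKOs))
    presence <- matrix(stats::rbinom(length(species) * nKOs, 1, presenceProb),
                       length(species), nKOs,
                       dimnames = list(species, kos))
    modules <- lapply(seq_len(nModules), function(m) {
        nSteps <- sample(1:4, 1)
        steps <- lapply(seq_len(nSteps), function(s)
            sample(kos, sample(1:3, 1)))
        list(id = sprintf("MF%04d", m),
             name = sprintf("synthetic module %d", m),
             steps = steps)
    })
    list(presence = presence, modules = modules)
}

#' Simulate a cohort for logistic coefficient recovery
#'
#' Draws one continuous exposure plus independent nuisance covariates (age,
#' sex, centre) and assigns a binary dysbiosis status from a logistic model
#' with a planted per-unit relative risk, the intercept tuned to a target
#' marginal prevalence at the exposure mean.
#'
#' @param n subjects.
#' @param xName name of the exposure column.
#' @param xMean,xSD exposure distribution.
#' @param rr planted per-unit relative risk; the log-odds coefficient is
#'   \code{log(rr)}.
#' @param prevalence target prevalence at the exposure mean.
#' @param seed seed.
#' @param nCenters recruitment centres.
#' @return data.frame with the exposure, age, sex, center and \code{bact2}
#'   (0/1).
#' @examples
#' d <- simulateLogisticCohort(500, "richness", 490, 120, rr = 0.98, seed = 1)
#' mean(d$bact2)
#' @export
simulateLogisticCohort <- function(n, xName = "richness", xMean = 490,
                                   xSD = 120, rr = 0.98, prevalence = 0.2,
                                   seed = 1L, nCenters = 5) {
    if (rr <= 0) stop("relative risk must be positive")
    set.seed(seed)
    x <- stats::rnorm(n, xMean, xSD)
    beta <- log(rr)
    a <- stats::qlogis(prevalence) - beta * xMean
    d <- data.frame(age = .rnormTrunc(n, 50.6, 9.9, 18),
                    sex = ifelse(stats::runif(n) < 0.209, "M", "F"),
                    center = sample(sprintf("C%02d", seq_len(nCenters)), n,
                                    replace = TRUE))
    d[[xName]] <- x
    d$bact2 <- as.integer(stats::runif(n) < stats::plogis(a + beta * x))
    d
}
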