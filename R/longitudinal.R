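## ---------------------------------------------------------------------------
## longitudinal: paired-visit analyses — baseline-diversity stratification,
## fold-change comparisons, enterotype transition tests, per-feature linear
## mixed models, and the paired clinical summary table.
## ---------------------------------------------------------------------------

#' Median split on baseline diversity
#'
#' Subjects at or below the median of the reference set go to the "low"
#' stratum, the rest to "high". The reference defaults to the values
#' themselves but is typically the full baseline cohort while the split is
#' applied to the paired subset.
#'
#' @param richness named numeric vector (per subject).
#' @param reference values over which the median threshold is computed.
#' @return factor (levels low/high) named like \code{richness}, with the
#'   threshold in the \code{"threshold"} attribute.
#' @examples
#' stratifyByMedian(setNames(1:10, paste0("s", 1:10)))
#' @export
stratifyByMedian <- function(richness, reference = richness) {
    if (!length(reference)) stop("empty reference set")
    med <- stats::median(reference, na.rm = TRUE)
    if (all(richness == richness[1]))
        warning("all richness values equal; every subject goes to 'low'")
    s <- factor(ifelse(richness <= med, "low", "high"),
                levels = c("low", "high"))
    names(s) <- names(richness)
    attr(s, "threshold") <- med
    s
}

#' Compare per-subject fold changes between strata
#'
#' Fold change = visit-2 value / visit-1 value per subject. Strata are
#' compared with a two-sample Wilcoxon rank-sum test (two independent groups);
#' the within-stratum change is tested against 1 with a Wilcoxon signed-rank
#' test. Subjects with a zero baseline value are excluded and logged.
#'
#' @param v1,v2 named numeric vectors (per subject), matched by name.
#' @param strata factor per subject (low/high), matched by name.
#' @param log use log fold-changes (ratio is the default).
#' @return list with \code{foldChanges} (data.frame subject, stratum, fc),
#'   \code{betweenP} (rank-sum p), \code{withinP} (named signed-rank p per
#'   stratum) and \code{excluded}.
#' @export
compareFoldChanges <- function(v1, v2, strata, log = FALSE) {
    subj <- intersect(names(v1), names(v2))
    if (!length(subj)) stop("no paired subjects")
    v1 <- v1[subj]; v2 <- v2[subj]; strata <- strata[subj]
    zero <- subj[v1 == 0]
    if (length(zero)) {
        message("excluded subject(s) with zero baseline: ",
                paste(zero, collapse = ", "))
        keep <- v1 != 0
        v1 <- v1[keep]; v2 <- v2[keep]; strata <- strata[keep]
        subj <- subj[keep]
    }
    fc <- v2 / v1
    if (log) fc <- base::log(fc)
    null <- if (log) 0 else 1
    strata <- droplevels(as.factor(strata))
    betweenP <- if (nlevels(strata) == 2)
        suppressWarnings(stats::wilcox.test(fc ~ strata)$p.value)
    else NA_real_
    withinP <- vapply(levels(strata), function(s) {
        v <- fc[strata == s]
        if (length(v) < 2 || all(v == null)) return(NA_real_)
        suppressWarnings(stats::wilcox.test(v, mu = null)$p.value)
    }, numeric(1))
    list(foldChanges = data.frame(subject = subj, stratum = strata, fc = fc,
                                  row.names = NULL, stringsAsFactors = FALSE),
         betweenP = betweenP, withinP = withinP, excluded = zero)
}

#' Enterotype transition analysis
#'
#' Tabulates visit-1 to visit-2 label transitions, tests the change in
#' marginal label prevalence with a chi-square test on the 2 x K table of
#' visit by label counts (a Stuart-Maxwell marginal-homogeneity test of the
#' paired transition table is available as an option), and reports every
#' observed switch fraction as numerator/denominator with a rounded percent.
#'
#' @param labelsV1,labelsV2 named label vectors (per subject), matched by
#'   name.
#' @param method "marginal" (default, chi-square on the 2 x K prevalence
#'   table) or "stuart-maxwell".
#' @return list with \code{transitions} (K x K from/to table),
#'   \code{marginals}, \code{statistic}, \code{df}, \code{p}, and
#'   \code{switches} (data.frame from, to, n, denom, percent).
#' @examples
#' v1 <- setNames(rep(c("A", "B"), c(4, 4)), paste0("s", 1:8))
#' v2 <- v1; v2[1:2] <- "B"
#' transitionTest(v1, v2)$switches
#' @export
transitionTest <- function(labelsV1, labelsV2,
                           method = c("marginal", "stuart-maxwell")) {
    method <- match.arg(method)
    subj <- intersect(names(labelsV1), names(labelsV2))
    if (length(subj) < 2) stop("need paired labels for >= 2 subjects")
    l1 <- as.character(labelsV1[subj]); l2 <- as.character(labelsV2[subj])
    levs <- sort(unique(c(l1, l2)))
    trans <- table(factor(l1, levs), factor(l2, levs), dnn = c("from", "to"))
    marg <- rbind(V1 = table(factor(l1, levs)), V2 = table(factor(l2, levs)))
    if (method == "marginal") {
        exp0 <- outer(rowSums(marg), colSums(marg)) / sum(marg)
        use <- colSums(marg) > 0
        stat <- sum((marg[, use] - exp0[, use])^2 / exp0[, use])
        df <- sum(use) - 1
        if (mean(exp0[, use] < 1) > 0.2)
            warning("more than 20% of expected cells < 1; ",
                    "consider an exact test")
    } else {
        ## Stuart-Maxwell marginal homogeneity on the paired table
        dvec <- rowSums(trans) - colSums(trans)
        k <- length(levs)
        S <- matrix(0, k, k)
        for (a in seq_len(k)) for (b in seq_len(k)) {
            S[a, b] <- if (a == b)
                sum(trans[a, ]) + sum(trans[, a]) - 2 * trans[a, a]
            else -(trans[a, b] + trans[b, a])
        }
        use <- seq_len(k - 1)
        stat <- tryCatch(
            as.numeric(t(dvec[use]) %*% solve(S[use, use]) %*% dvec[use]),
            error = function(e) 0)
        df <- k - 1
    }
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    sw <- as.data.frame(trans, stringsAsFactors = FALSE)
    names(sw) <- c("from", "to", "n")
    denom <- rowSums(trans)[sw$from]
    sw$denom <- as.integer(denom)
    sw$percent <- ifelse(sw$denom > 0, round(100 * sw$n / sw$denom),
                         NA_real_)
    list(transitions = trans, marginals = marg, statistic = stat, df = df,
         p = p, switches = sw[sw$denom > 0, ])
}

#' Per-feature linear mixed model of the visit effect
#'
#' y = b0 + b1 visit + u_subject (+ v_lmp) + e with random intercepts, fitted
#' by REML (\pkg{lme4}); the visit coefficient is the V2-vs-V1 shift. The
#' optional LMP intake random factor absorbs supplement-driven variability; it
#' is dropped (with a message) when it has fewer than 2 levels. Wald test on
#' the visit coefficient.
#'
#' @param y feature values, one per sample.
#' @param visit factor/character with two levels (baseline first).
#' @param subject subject id per sample.
#' @param lmp optional LMP intake flag per sample.
#' @return one-row data.frame: beta (visit effect), se, p, variance
#'   components (\code{var_subject}, \code{var_lmp}, \code{var_residual}),
#'   convergence and degeneracy flags.
#' @export
lmmFeature <- function(y, visit, subject, lmp = NULL) {
    visit <- as.factor(visit)
    if (nlevels(visit) != 2) stop("visit must have exactly 2 levels")
    paired <- length(unique(subject[duplicated(subject)]))
    if (paired < 2) stop("need >= 2 subjects with both visits")
    if (stats::var(y) == 0)
        return(data.frame(beta = 0, se = NA_real_, p = NA_real_,
                          var_subject = 0, var_lmp = NA_real_,
                          var_residual = 0, converged = TRUE,
                          degenerate = TRUE))
    d <- data.frame(y = y, visit = visit, subject = factor(subject))
    useLmp <- FALSE
    if (!is.null(lmp)) {
        if (length(unique(lmp)) >= 2) {
            d$lmp <- factor(lmp)
            useLmp <- TRUE
        } else message("LMP factor has < 2 levels; subject-only model used")
    }
    f <- if (useLmp) y ~ visit + (1 | subject) + (1 | lmp) else
        y ~ visit + (1 | subject)
    fit <- tryCatch(
        suppressMessages(suppressWarnings(lme4::lmer(f, data = d,
                                                     REML = TRUE))),
        error = function(e) NULL)
    if (is.null(fit))   # e.g. zero residual variance within subjects
        return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                          var_subject = NA_real_, var_lmp = NA_real_,
                          var_residual = NA_real_, converged = FALSE,
                          degenerate = TRUE))
    sm <- summary(fit)$coefficients
    beta <- sm[2, 1]; se <- sm[2, 2]
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) {
        v <- vc$vcov[vc$grp == g]
        if (length(v)) v[1] else NA_real_
    }
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    data.frame(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
               var_subject = getv("subject"), var_lmp = getv("lmp"),
               var_residual = getv("Residual"),
               converged = conv, degenerate = FALSE)
}

#' Visit effect across a feature family
#'
#' Runs \code{\link{lmmFeature}} on every column and applies BH correction
#' across the family.
#'
#' @param features samples x features matrix (rows aligned with the design).
#' @param visit,subject,lmp per-sample design vectors (see
#'   \code{\link{lmmFeature}}).
#' @return data.frame, one row per feature, with q-values.
#' @export
lmmFeatures <- function(features, visit, subject, lmp = NULL) {
    features <- as.matrix(features)
    res <- do.call(rbind, lapply(colnames(features), function(j) {
        r <- lmmFeature(features[, j], visit, subject, lmp)
        r$feature <- j
        r
    }))
    res$q <- bhAdjust(res$p)
    res[, c("feature", setdiff(names(res), "feature"))]
}

#' Paired clinical summary
#'
#' Two-tailed paired Student t-tests per clinical variable between baseline
#' and follow-up, with the conventional significance stars (ns, *, **, ***,
#' **** at 0.05 / 0.01 / 0.001 / 0.0001). Variables with fewer than 3 pairs
#' are skipped.
#'
#' @param clinical data.frame with \code{subject_id} and \code{visit}
#'   columns (levels V1/V2) plus numeric variables.
#' @param variables columns to summarise (default: all shared numeric ones).
#' @return data.frame: variable, n, mean_V1, sd_V1, mean_V2, sd_V2, t, p,
#'   stars.
#' @export
pairedClinical <- function(clinical, variables = NULL) {
    c1 <- clinical[clinical$visit == "V1", ]
    c2 <- clinical[clinical$visit == "V2", ]
    subj <- intersect(c1$subject_id, c2$subject_id)
    c1 <- c1[match(subj, c1$subject_id), ]
    c2 <- c2[match(subj, c2$subject_id), ]
    if (is.null(variables))
        variables <- names(clinical)[vapply(clinical, is.numeric,
                                            logical(1))]
    out <- list()
    for (v in variables) {
        x1 <- c1[[v]]; x2 <- c2[[v]]
        ok <- stats::complete.cases(x1, x2)
        if (sum(ok) < 3) next
        x1 <- x1[ok]; x2 <- x2[ok]
        if (all(x1 == x2)) {
            tt <- list(statistic = 0, p.value = 1)
        } else {
            tt <- stats::t.test(x2, x1, paired = TRUE)
        }
        p <- tt$p.value
        stars <- cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                     labels = c("****", "***", "**", "*", "ns"))
        out[[v]] <- data.frame(variable = v, n = sum(ok),
                               mean_V1 = mean(x1), sd_V1 = stats::sd(x1),
                               mean_V2 = mean(x2), sd_V2 = stats::sd(x2),
                               t = unname(tt$statistic), p = p,
                               stars = as.character(stars),
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
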