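## ---------------------------------------------------------------------------
## association: adjusted linear/logistic regressions, enterotype-feature
## enrichment (Kruskal-Wallis + Dunn + Cliff's delta), BH correction.
## "Relative risk" is reported as exp(beta) from the logistic model — the
## operational definition used in the cohort analyses this package mirrors
## (it is an odds ratio in strict epidemiological terms; see the vignette).
## ---------------------------------------------------------------------------

.dropIncomplete <- function(data, vars) {
    cc <- stats::complete.cases(data[, vars, drop = FALSE])
    if (!all(cc))
        message(sum(!cc), " row(s) dropped for missing values")
    data[cc, , drop = FALSE]
}

#' Adjusted linear association
#'
#' Ordinary least squares of a per-sample index (e.g. species richness) on one
#' covariate plus an adjustment set, with two-tailed Wald p-values. With
#' \code{standardize = TRUE} the outcome and a numeric covariate are z-scored
#' first, so the coefficient is a standardized beta.
#'
#' @param data data.frame of per-sample values.
#' @param outcome name of the numeric outcome column.
#' @param covariate name of the covariate of interest.
#' @param adjust character vector of confounder columns (default none).
#' @param standardize z-score outcome and numeric covariate before fitting.
#' @return data.frame, one row per non-reference level of the covariate, with
#'   \code{beta}, \code{se}, \code{p}, \code{n_used} and the adjustment set.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' linearAssoc(d, "y", "x")
#' @export
linearAssoc <- function(data, outcome, covariate, adjust = character(),
                        standardize = FALSE) {
    vars <- c(outcome, covariate, adjust)
    data <- .dropIncomplete(as.data.frame(data), vars)
    y <- data[[outcome]]
    if (!is.numeric(y)) stop("outcome must be numeric")
    if (standardize) {
        data[[outcome]] <- as.numeric(scale(y))
        if (is.numeric(data[[covariate]]))
            data[[covariate]] <- as.numeric(scale(data[[covariate]]))
    }
    f <- stats::reformulate(c(covariate, adjust), response = outcome)
    fit <- stats::lm(f, data = data)
    if (any(is.na(stats::coef(fit)))) {
        bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    sm <- summary(fit)$coefficients
    rows <- grep(paste0("^", covariate), rownames(sm))
    data.frame(outcome = outcome, covariate = covariate,
               term = rownames(sm)[rows],
               beta = sm[rows, 1], se = sm[rows, 2], p = sm[rows, 4],
               n_used = length(stats::residuals(fit)),
               adjustment = paste(adjust, collapse = "+"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted logistic association with relative-risk scaling
#'
#' Maximum-likelihood logistic regression (IRLS via \code{glm}) of a binary
#' status (e.g. Bact2 membership) on a covariate plus confounders. The
#' exponentiated coefficient is reported as the relative risk per unit of the
#' covariate together with its Wald 95% interval. Quasi-complete separation is
#' detected (non-convergence or exploding coefficients) and flagged rather
#' than silently reported.
#'
#' @param data data.frame.
#' @param outcome name of the binary (0/1 or logical) outcome column.
#' @param covariate covariate of interest.
#' @param adjust confounder columns.
#' @return data.frame with \code{beta}, \code{se}, \code{p}, \code{rr},
#'   \code{rr_lo}, \code{rr_hi}, \code{separation} flag, \code{n_used}. A
#'   \code{"curve"} attribute carries the predicted-probability curve over the
#'   observed covariate range (numeric covariates, confounders at their
#'   reference/mean).
#' @examples
#' d <- simulateLogisticCohort(300, "bmi", 32.8, 4.9, rr = 1.3, seed = 1)
#' logisticAssoc(d, "bact2", "bmi", adjust = c("age", "sex"))
#' @export
logisticAssoc <- function(data, outcome, covariate, adjust = character()) {
    vars <- c(outcome, covariate, adjust)
    data <- .dropIncomplete(as.data.frame(data), vars)
    y <- data[[outcome]]
    if (is.logical(y)) y <- as.integer(y)
    if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
    if (length(unique(y)) < 2) stop("outcome has a single class")
    data[[outcome]] <- y
    f <- stats::reformulate(c(covariate, adjust), response = outcome)
    fit <- suppressWarnings(stats::glm(f, data = data,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    rows <- grep(paste0("^", covariate), rownames(sm))
    sep <- !fit$converged || any(abs(sm[rows, 1]) > 15) ||
        any(sm[rows, 2] > 100)
    if (sep)
        warning("possible quasi-complete separation for ", covariate)
    z <- stats::qnorm(0.975)
    res <- data.frame(outcome = outcome, covariate = covariate,
                      term = rownames(sm)[rows],
                      beta = sm[rows, 1], se = sm[rows, 2], p = sm[rows, 4],
                      rr = exp(sm[rows, 1]),
                      rr_lo = exp(sm[rows, 1] - z * sm[rows, 2]),
                      rr_hi = exp(sm[rows, 1] + z * sm[rows, 2]),
                      separation = sep,
                      n_used = length(stats::residuals(fit)),
                      adjustment = paste(adjust, collapse = "+"),
                      row.names = NULL, stringsAsFactors = FALSE)
    if (is.numeric(data[[covariate]])) {
        grid <- data.frame(seq(min(data[[covariate]]),
                               max(data[[covariate]]), length.out = 100))
        names(grid) <- covariate
        for (a in adjust) {
            grid[[a]] <- if (is.numeric(data[[a]])) mean(data[[a]]) else
                sort(unique(data[[a]]))[1]
        }
        grid$predicted <- stats::predict(fit, newdata = grid,
                                         type = "response")
        attr(res, "curve") <- grid
    }
    res
}

#' Cliff's delta effect size
#'
#' delta = (#\{x > y\} - #\{x < y\}) / (n_x n_y): the difference between the
#' probabilities that a value of one group exceeds a value of the other.
#'
#' @param x,y numeric vectors.
#' @return delta in [-1, 1].
#' @examples
#' cliffsDelta(c(1, 2, 3), c(2, 3, 4))
#' @export
cliffsDelta <- function(x, y) {
    s <- sign(outer(x, y, `-`))
    sum(s) / (length(x) * length(y))
}

## Dunn post-hoc z-test on joint ranks with tie correction; returns two-sided p
.dunn <- function(ranksByGroup, N, tieTerm) {
    function(a, b) {
        na <- length(ranksByGroup[[a]]); nb <- length(ranksByGroup[[b]])
        z <- (mean(ranksByGroup[[a]]) - mean(ranksByGroup[[b]])) /
            sqrt((N * (N + 1) / 12 - tieTerm) * (1 / na + 1 / nb))
        2 * stats::pnorm(-abs(z))
    }
}

#' Enterotype-feature enrichment
#'
#' For each feature: a Kruskal-Wallis test across all enterotype groups, and
#' for every pairwise contrast of the focal group (default Bact2) versus each
#' other group a Dunn post-hoc z-test (joint ranks, tie-corrected) and Cliff's
#' delta. BH correction is applied per family: the Kruskal-Wallis p-values
#' over features, and the Dunn p-values over features within each contrast.
#'
#' @param features numeric matrix or data.frame, samples x features.
#' @param labels enterotype label per sample.
#' @param focal label of the focal group (default "Bact2").
#' @return data.frame in long format: feature, kw_p, kw_q, contrast, dunn_p,
#'   dunn_q, cliffs_delta. Contrasts against groups with fewer than 2 samples
#'   are skipped with a warning.
#' @export
enterotypeFeatureEnrichment <- function(features, labels, focal = "Bact2") {
    features <- as.matrix(features)
    labels <- as.character(labels)
    stopifnot(nrow(features) == length(labels))
    grps <- unique(labels)
    small <- grps[table(labels)[grps] < 2]
    if (length(small)) {
        warning("group(s) with < 2 samples skipped: ",
                paste(small, collapse = ", "))
        keep <- labels %in% setdiff(grps, small)
        features <- features[keep, , drop = FALSE]
        labels <- labels[keep]
        grps <- setdiff(grps, small)
    }
    if (!focal %in% grps) stop("focal group '", focal, "' not present")
    others <- setdiff(grps, focal)
    out <- list()
    for (j in colnames(features)) {
        v <- features[, j]
        kw <- stats::kruskal.test(v, factor(labels))$p.value
        r <- rank(v)
        N <- length(v)
        ties <- table(v)
        tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
        rg <- split(r, labels)
        dunnP <- .dunn(rg, N, tieTerm)
        vg <- split(v, labels)
        for (o in others) {
            out[[length(out) + 1]] <- data.frame(
                feature = j, kw_p = kw,
                contrast = paste(focal, "vs", o),
                dunn_p = dunnP(focal, o),
                cliffs_delta = cliffsDelta(vg[[focal]], vg[[o]]),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    kwPerFeature <- !duplicated(res$feature)
    kwq <- bhAdjust(res$kw_p[kwPerFeature])
    res$kw_q <- kwq[match(res$feature, res$feature[kwPerFeature])]
    res$dunn_q <- NA_real_
    for (ct in unique(res$contrast)) {
        idx <- res$contrast == ct
        res$dunn_q[idx] <- bhAdjust(res$dunn_p[idx])
    }
    res[, c("feature", "kw_p", "kw_q", "contrast", "dunn_p", "dunn_q",
            "cliffs_delta")]
}

#' Benjamini-Hochberg adjustment
#'
#' Monotone step-up FDR adjustment: q_i = min over j with p_j >= p_i of
#' min(1, m p_j / rank_j).
#'
#' @param p vector of p-values in [0, 1] (NAs passed through).
#' @return vector of q-values (q >= p elementwise).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
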