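## ---------------------------------------------------------------------------
## matching: propensity-score construction and greedy 1:1 nearest-neighbour
## matching of supplement consumers to non-consumers, without replacement
## (equal-sized exhaustive groups), with balance diagnostics.
## ---------------------------------------------------------------------------

## standardized mean difference; factors are expanded to indicators upstream
.smd <- function(x, treated) {
    mt <- mean(x[treated]); mc <- mean(x[!treated])
    s <- sqrt((stats::var(x[treated]) + stats::var(x[!treated])) / 2)
    if (s == 0) return(0)
    (mt - mc) / s
}

#' Propensity-score 1:1 matching
#'
#' Fits a logistic propensity model of treatment on the stated covariates and
#' matches greedily on the logit propensity scale: treated units are
#' processed in descending propensity order, each taking the nearest
#' still-unmatched control (ties by row order, hence by subject id order of
#' the input). Matching is without replacement, so with fewer controls than
#' treated every control is used exactly once. An optional caliper is
#' expressed as a multiple of the logit-propensity standard deviation.
#'
#' @param data data.frame, one row per subject.
#' @param treatment name of the logical/binary treatment column
#'   (default "LMP").
#' @param covariates matching covariates (default age, sex, weight).
#' @param caliper optional caliper in logit-PS standard deviations; pairs
#'   farther apart are not formed.
#' @param id name of the subject id column, or NULL to use row names.
#' @return list with \code{pairs} (treated, control, distance),
#'   \code{unmatched} (ids), and \code{balance} (per-covariate standardized
#'   mean differences before/after matching).
#' @examples
#' set.seed(1)
#' d <- data.frame(age = rnorm(60, 50, 10), sex = sample(c("M", "F"), 60, TRUE),
#'                 weight = rnorm(60, 90, 15), LMP = rep(c(TRUE, FALSE), c(40, 20)))
#' m <- propensityMatch(d)
#' nrow(m$pairs)  # 20: every control matched
#' @export
propensityMatch <- function(data, treatment = "LMP",
                            covariates = c("age", "sex", "weight"),
                            caliper = NULL, id = NULL) {
    data <- as.data.frame(data)
    ids <- if (is.null(id)) {
        if (is.null(rownames(data))) as.character(seq_len(nrow(data)))
        else rownames(data)
    } else as.character(data[[id]])
    tr <- data[[treatment]]
    if (is.logical(tr)) tr <- as.integer(tr)
    if (!all(tr %in% c(0, 1))) stop("treatment must be binary")
    if (!any(tr == 1) || !any(tr == 0))
        stop("both treatment groups must be non-empty")
    f <- stats::reformulate(covariates, response = treatment)
    d2 <- data; d2[[treatment]] <- tr
    fit <- suppressWarnings(stats::glm(f, data = d2,
                                       family = stats::binomial()))
    cf <- stats::coef(fit)
    if (any(is.na(cf)))
        stop("propensity model is rank deficient; collinear covariate(s): ",
             paste(names(cf)[is.na(cf)], collapse = ", "))
    if (!fit$converged || any(abs(cf) > 15))
        stop("propensity model separation; review the covariates")
    ps <- stats::fitted(fit)
    lp <- stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
    maxDist <- if (is.null(caliper)) Inf else caliper * stats::sd(lp)

    treatedIdx <- which(tr == 1)
    controlIdx <- which(tr == 0)
    treatedIdx <- treatedIdx[order(-ps[treatedIdx], ids[treatedIdx])]
    free <- rep(TRUE, length(controlIdx))
    pairs <- list()
    for (t in treatedIdx) {
        if (!any(free)) break
        cand <- controlIdx[free]
        dd <- abs(lp[cand] - lp[t])
        j <- which.min(dd)
        if (dd[j] <= maxDist) {
            pairs[[length(pairs) + 1]] <- data.frame(
                treated = ids[t], control = ids[cand[j]],
                distance = dd[j], stringsAsFactors = FALSE)
            free[match(cand[j], controlIdx)] <- FALSE
        }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
        data.frame(treated = character(), control = character(),
                   distance = numeric())
    matchedIds <- c(pairs$treated, pairs$control)
    unmatched <- setdiff(ids, matchedIds)

    ## balance: numeric covariates + indicators for factor levels
    X <- stats::model.matrix(stats::reformulate(covariates), data = d2)
    X <- X[, -1, drop = FALSE]
    after <- ids %in% matchedIds
    balance <- do.call(rbind, lapply(colnames(X), function(v) data.frame(
        covariate = v,
        smd_before = .smd(X[, v], tr == 1),
        smd_after = if (any(after)) .smd(X[after, v], tr[after] == 1)
        else NA_real_,
        stringsAsFactors = FALSE)))
    list(pairs = pairs, unmatched = unmatched, balance = balance,
         propensity = stats::setNames(ps, ids))
}
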