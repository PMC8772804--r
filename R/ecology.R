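## ---------------------------------------------------------------------------
## ecology: alpha/beta diversity, PCoA, dbRDA, PERMANOVA.
## dbRDA follows the classical construction: redundancy analysis on the
## positive-eigenvalue principal coordinates of the distance matrix, with
## Ezekiel-adjusted R2 and permutation p-values on the pseudo-F statistic.
## ---------------------------------------------------------------------------

#' Per-sample alpha diversity
#'
#' Richness S (taxa with positive count) and Shannon entropy
#' H = -sum p log p (natural log). Requires a rarefied table (equal row sums):
#' diversity on unrarefied counts is depth-biased and is refused.
#'
#' @param x an \linkS4class{AbundanceTable} with equal row sums
#'   (e.g. the output of \code{\link{rarefy}}).
#' @return data.frame with \code{sample_id}, \code{richness},
#'   \code{shannon} and \code{evenness} (H / log S; NA when S = 1).
#' @examples
#' m <- matrix(c(5, 5, 5, 10, 0, 5), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' alphaDiversity(abundanceTable(m, depth = 15))
#' @export
alphaDiversity <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    m <- abundances(x)
    rs <- rowSums(m)
    if (is.na(rarefiedDepth(x)) && length(unique(rs)) > 1)
        stop("alphaDiversity requires equal sampling depth; rarefy first")
    p <- m / rs
    H <- apply(p, 1, function(pi) {
        pi <- pi[pi > 0]
        -sum(pi * log(pi))
    })
    S <- rowSums(m > 0)
    data.frame(sample_id = rownames(m), richness = as.integer(S),
               shannon = H,
               evenness = ifelse(S > 1, H / log(S), NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' D_xy = 1 - sum_j min(p_xj, p_yj) for relative abundance rows (equivalently
#' half the L1 distance between profiles).
#'
#' @param x a relative \linkS4class{AbundanceTable} (counts are normalised on
#'   the fly; all-zero rows are an error).
#' @return a \code{\link[stats]{dist}} object with entries in [0, 1].
#' @examples
#' m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.25, 0.25, 0.5))
#' colnames(m) <- c("A", "B", "C")
#' brayCurtis(abundanceTable(m, relative = TRUE))  # 0.5
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "AbundanceTable")) abundances(x) else as.matrix(x)
    rs <- rowSums(m)
    if (any(rs == 0))
        stop("Bray-Curtis undefined for all-zero sample(s): ",
             paste(rownames(m)[rs == 0], collapse = ", "))
    p <- m / rs
    stats::dist(p, method = "manhattan") / 2
}

#' Principal coordinate analysis
#'
#' Classical scaling (Torgerson) of the double-centred -D^2/2 matrix.
#' Coordinates are returned for axes with positive eigenvalues; the relative
#' mass of negative eigenvalues is reported.
#'
#' @param d a \code{dist} or symmetric matrix with zero diagonal.
#' @return list with \code{coordinates} (samples x positive axes, scaled by
#'   sqrt(eigenvalue)), \code{eigenvalues} (all, descending) and
#'   \code{negativeMass} (sum |negative| / sum |all|).
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' p <- pcoa(dist(pts))
#' sum(p$eigenvalues > 1e-8)  # 2: planar configuration
#' @export
pcoa <- function(d) {
    if (!inherits(d, "dist")) {
        d <- as.matrix(d)
        if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12))
            stop("distance input must be symmetric with zero diagonal")
        d <- stats::as.dist(d)
    }
    n <- attr(d, "Size")
    cs <- stats::cmdscale(d, k = n - 1, eig = TRUE)
    eig <- cs$eig
    tol <- 1e-8 * max(abs(eig), 1)
    pos <- which(eig > tol)
    coords <- cs$points[, seq_along(pos), drop = FALSE]
    colnames(coords) <- paste0("PCo", seq_along(pos))
    list(coordinates = coords, eigenvalues = eig,
         negativeMass = sum(abs(pmin(eig, 0))) / sum(abs(eig)))
}

## R2 of covariate block X (data.frame/vector) on centred axes Y
.rdaR2 <- function(Y, X) {
    X <- as.data.frame(X)
    mm <- stats::model.matrix(~ ., data = X)[, -1, drop = FALSE]
    mm <- scale(mm, center = TRUE, scale = FALSE)
    q <- qr(mm)
    if (q$rank == 0) stop("degenerate (constant) covariate")
    fit <- qr.fitted(q, Y)
    list(R2 = sum(fit^2) / sum(Y^2), q = q$rank)
}

.ezekiel <- function(R2, n, q) 1 - (1 - R2) * (n - 1) / (n - 1 - q)

#' Univariate distance-based redundancy analysis
#'
#' Fraction of beta-diversity inertia explained by one covariate: redundancy
#' analysis on the positive-eigenvalue PCoA axes of \code{d}, with a
#' permutation test of the pseudo-F statistic (covariate rows permuted).
#'
#' @param d distance matrix (\code{dist} or symmetric matrix).
#' @param covariate vector (numeric or factor), one value per sample;
#'   categoricals are expanded to indicator contrasts.
#' @param nPerm number of permutations (default 999).
#' @param seed seed of the permutation stream.
#' @return data.frame with \code{R2}, \code{adjR2} (Ezekiel), \code{F},
#'   \code{p} (floored at 1/(nPerm+1)) and \code{nPerm}.
#' @examples
#' set.seed(1)
#' m <- matrix(rexp(60), 10, 6,
#'             dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
#' d <- brayCurtis(abundanceTable(m))
#' dbrdaUnivariate(d, rnorm(10), nPerm = 99, seed = 1)
#' @export
dbrdaUnivariate <- function(d, covariate, nPerm = 999, seed = 1L) {
    Y <- pcoa(d)$coordinates
    n <- nrow(Y)
    if (length(covariate) != n)
        stop("covariate must have one value per sample")
    if (length(unique(covariate)) < 2) stop("degenerate (constant) covariate")
    r <- .rdaR2(Y, covariate)
    Fobs <- (r$R2 / r$q) / ((1 - r$R2) / (n - 1 - r$q))
    set.seed(seed)
    Fperm <- replicate(nPerm, {
        rp <- .rdaR2(Y, sample(covariate))
        (rp$R2 / rp$q) / ((1 - rp$R2) / (n - 1 - rp$q))
    })
    p <- (1 + sum(Fperm >= Fobs)) / (nPerm + 1)
    data.frame(R2 = r$R2, adjR2 = .ezekiel(r$R2, n, r$q), F = Fobs, p = p,
               nPerm = nPerm)
}

#' Forward stepwise distance-based redundancy analysis
#'
#' At each step the candidate maximising the cumulative adjusted R2 is tested
#' by permutation (conditional pseudo-F, candidate rows permuted); it enters
#' if p <= \code{alphaIn} and the cumulative adjusted R2 stays at or below the
#' full-model adjusted R2 — the classical adjusted-R2 stopping rule guarding
#' against over-selection.
#'
#' @param d distance matrix.
#' @param covariates data.frame of candidate covariates (>= 2 columns).
#' @param alphaIn entry significance level (default 0.05).
#' @param nPerm permutations per entry test.
#' @param seed seed.
#' @return data.frame, one row per selected covariate in entry order, with
#'   cumulative \code{R2}, \code{adjR2} and the entry \code{p}; zero rows when
#'   nothing enters.
#' @export
dbrdaStepwise <- function(d, covariates, alphaIn = 0.05, nPerm = 999,
                          seed = 1L) {
    covariates <- as.data.frame(covariates)
    if (ncol(covariates) < 2) stop("need >= 2 candidate covariates")
    Y <- pcoa(d)$coordinates
    n <- nrow(Y)
    full <- .rdaR2(Y, covariates)
    fullAdj <- .ezekiel(full$R2, n, full$q)
    set.seed(seed)
    selected <- character()
    out <- data.frame(covariate = character(), R2 = numeric(),
                      adjR2 = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
    repeat {
        remaining <- setdiff(names(covariates), selected)
        if (!length(remaining)) break
        cand <- vapply(remaining, function(v) {
            r <- .rdaR2(Y, covariates[c(selected, v)])
            .ezekiel(r$R2, n, r$q)
        }, numeric(1))
        best <- remaining[which.max(cand)]
        if (cand[best] > fullAdj + 1e-12) break
        ## conditional permutation test for the candidate term
        base <- if (length(selected))
            .rdaR2(Y, covariates[selected])$R2 else 0
        r1 <- .rdaR2(Y, covariates[c(selected, best)])
        qAdd <- r1$q - if (length(selected))
            .rdaR2(Y, covariates[selected])$q else 0
        if (qAdd == 0) break   # candidate adds no rank (e.g. a duplicate)
        Fobs <- ((r1$R2 - base) / qAdd) /
            ((1 - r1$R2) / (n - 1 - r1$q))
        Fperm <- replicate(nPerm, {
            cv <- covariates[c(selected, best)]
            cv[[best]] <- sample(cv[[best]])
            rp <- .rdaR2(Y, cv)
            ((rp$R2 - base) / qAdd) / ((1 - rp$R2) / (n - 1 - rp$q))
        })
        p <- (1 + sum(Fperm >= Fobs)) / (nPerm + 1)
        if (p > alphaIn) break
        selected <- c(selected, best)
        out <- rbind(out, data.frame(covariate = best, R2 = r1$R2,
                                     adjR2 = .ezekiel(r1$R2, n, r1$q),
                                     p = p, stringsAsFactors = FALSE))
    }
    out
}

## Anderson partition of squared distances for a grouping factor
.permanovaF <- function(d2, group) {
    n <- nrow(d2)
    SST <- sum(d2[lower.tri(d2)]) / n
    SSW <- 0
    for (g in unique(group)) {
        idx <- which(group == g)
        if (length(idx) > 1)
            SSW <- SSW + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) /
                length(idx)
    }
    a <- length(unique(group))
    SSB <- SST - SSW
    list(F = (SSB / (a - 1)) / (SSW / (n - a)), R2 = SSB / SST)
}

#' PERMANOVA for a single grouping factor
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (pseudo-F from the partition of squared inter-point distances). With
#' \code{strata}, permutations are restricted within strata — e.g. within
#' subjects for paired-visit designs.
#'
#' @param d distance matrix.
#' @param group grouping factor (>= 2 levels).
#' @param strata optional factor restricting permutations.
#' @param nPerm permutations (default 999).
#' @param seed seed.
#' @return data.frame with \code{R2}, pseudo-\code{F}, \code{p} and
#'   \code{nPerm}.
#' @examples
#' pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 4), 5))
#' permanova(dist(pts), rep(c("a", "b"), each = 5), nPerm = 99, seed = 1)
#' @export
permanova <- function(d, group, strata = NULL, nPerm = 999, seed = 1L) {
    d2 <- as.matrix(d)^2
    n <- nrow(d2)
    group <- as.factor(group)
    if (length(group) != n) stop("group must have one value per sample")
    if (nlevels(droplevels(group)) < 2)
        stop("PERMANOVA needs >= 2 groups; the grouping factor is constant")
    if (!is.null(strata)) {
        strata <- as.factor(strata)
        singles <- names(which(table(strata) < 2))
        if (length(singles))
            warning("strata with a single sample cannot permute: ",
                    paste(singles, collapse = ", "))
    }
    obs <- .permanovaF(d2, group)
    set.seed(seed)
    permuteIdx <- function() {
        if (is.null(strata)) return(sample.int(n))
        idx <- seq_len(n)
        for (s in levels(strata)) {
            w <- which(strata == s)
            if (length(w) > 1) idx[w] <- sample(w)
        }
        idx
    }
    cnt <- 0L
    for (b in seq_len(nPerm)) {
        Fp <- .permanovaF(d2, group[permuteIdx()])$F
        if (Fp >= obs$F - 1e-12) cnt <- cnt + 1L
    }
    data.frame(R2 = obs$R2, F = obs$F, p = (1 + cnt) / (nPerm + 1),
               nPerm = nPerm)
}
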