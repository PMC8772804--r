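## ---------------------------------------------------------------------------
## Dirichlet multinomial mixture enterotyping.
##
## EM with Minka-style fixed-point M-steps for the per-component Dirichlet
## parameters (a generalised EM: each M-step pass is derived from a bound
## guaranteeing a non-decreasing observed-data log-likelihood). Model order is
## selected by a Laplace-approximate log evidence with diagonal-plus-rank-one
## Hessian blocks per component, falling back to BIC when a block is not
## usable. Components are mapped to the semantic labels Bact1/Bact2/Rum/Bif
## by marker-genus dominance and expected Shannon diversity.
## ---------------------------------------------------------------------------

## log Dirichlet-multinomial probability of each row of x under alpha;
## logCoef is the multinomial coefficient term (constant across components)
.dmLogProb <- function(x, alpha, rowTotals, logCoef) {
    A <- sum(alpha)
    logCoef + lgamma(A) - lgamma(A + rowTotals) +
        rowSums(lgamma(x + rep(alpha, each = nrow(x)))) - sum(lgamma(alpha))
}

## one weighted Minka fixed-point pass for a component's alpha
.alphaFixedPoint <- function(x, alpha, w, rowTotals) {
    A <- sum(alpha)
    sw <- sum(w)
    num <- colSums(w * digamma(x + rep(alpha, each = nrow(x)))) -
        sw * digamma(alpha)
    den <- sum(w * digamma(rowTotals + A)) - sw * digamma(A)
    out <- alpha * num / den
    pmax(out, 1e-10)
}

.logsumexp <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
}

## initial alpha for a component from soft assignments: weighted mean
## composition at a moderate starting concentration
.alphaInit <- function(x, w, conc = 25) {
    p <- colSums(w * x) + 0.5
    conc * p / sum(p)
}

.emRun <- function(x, K, gamma0, tol, maxIter, rowTotals, logCoef) {
    N <- nrow(x); J <- ncol(x)
    alpha <- t(vapply(seq_len(K), function(k) .alphaInit(x, gamma0[, k]),
                      numeric(J)))
    pi <- pmax(colMeans(gamma0), 1e-8)
    pi <- pi / sum(pi)
    ll <- -Inf
    llTrace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        logp <- vapply(seq_len(K), function(k)
            .dmLogProb(x, alpha[k, ], rowTotals, logCoef), numeric(N))
        logp <- matrix(logp, N, K)
        logpost <- sweep(logp, 2, log(pi), `+`)
        lse <- .logsumexp(logpost)
        llNew <- sum(lse)
        gamma <- exp(logpost - lse)
        llTrace <- c(llTrace, llNew)
        if (is.finite(ll) && abs(llNew - ll) < tol * abs(llNew)) {
            ll <- llNew
            converged <- TRUE
            break
        }
        ll <- llNew
        if (iter >= maxIter) break
        pi <- pmax(colMeans(gamma), 1e-10)
        pi <- pi / sum(pi)
        for (k in seq_len(K))
            alpha[k, ] <- .alphaFixedPoint(x, alpha[k, ], gamma[, k],
                                           rowTotals)
    }
    list(pi = pi, alpha = alpha, gamma = gamma, ll = ll, llTrace = llTrace,
         converged = converged, iter = iter)
}

## Hessian part of the Laplace evidence: per-component diagonal + rank-one
## blocks of the responsibility-weighted DM log-likelihood. Returns the
## log-determinant and the free alpha-parameter count, or ok = FALSE when a
## block is not negative definite or a component is too thinly populated for
## an interior mode (fewer weighted samples than free parameters).
.laplaceHessian <- function(x, fit, rowTotals) {
    K <- length(fit$pi)
    logdet <- 0
    dAlpha <- 0L
    for (k in seq_len(K)) {
        alpha <- fit$alpha[k, ]
        active <- alpha > 1e-8     # floored parameters are boundary, not free
        w <- fit$gamma[, k]
        dAlpha <- dAlpha + sum(active)
        if (sum(w) < sum(active))
            return(list(ok = FALSE, dAlpha = NA_integer_))
        A <- sum(alpha)
        cK <- sum(w * (trigamma(A) - trigamma(A + rowTotals)))
        xa <- x[, active, drop = FALSE]
        aj <- alpha[active]
        e <- -(colSums(w * trigamma(xa + rep(aj, each = nrow(xa)))) -
                   sum(w) * trigamma(aj))
        if (any(e <= 1e-12)) return(list(ok = FALSE, dAlpha = NA_integer_))
        rank1 <- 1 - cK * sum(1 / e)
        if (rank1 <= 1e-12) return(list(ok = FALSE, dAlpha = NA_integer_))
        logdet <- logdet + sum(log(e)) + log(rank1)
    }
    list(ok = TRUE, logdet = logdet, dAlpha = dAlpha)
}

## Laplace-approximate log model evidence at the fitted mode, under a vague
## exponential prior on each free Dirichlet parameter (rate `priorRate`; zero
## curvature, so the Hessian is that of the log-likelihood). Mixture weights
## contribute a BIC-style (K-1)/2 log N term. When a Hessian block is
## unusable the d/2 log N unit-information surrogate replaces log|H|/2 (the
## BIC fallback, on the same prior-inclusive scale).
.laplaceEvidence <- function(x, fit, rowTotals, priorRate) {
    N <- nrow(x); K <- length(fit$pi)
    h <- .laplaceHessian(x, fit, rowTotals)
    activeAlpha <- sum(fit$alpha[fit$alpha > 1e-8])
    dAlpha <- if (h$ok) h$dAlpha else sum(fit$alpha > 1e-8)
    logPrior <- dAlpha * log(priorRate) - priorRate * activeAlpha
    base <- fit$ll + logPrior - (K - 1) / 2 * log(N)
    if (h$ok) {
        ev <- base + dAlpha / 2 * log(2 * pi) - h$logdet / 2
    } else {
        ev <- base + dAlpha / 2 * (log(2 * pi) - log(N))
    }
    list(evidence = ev, laplaceOK = h$ok)
}

.checkCountMatrix <- function(counts) {
    m <- if (is(counts, "AbundanceTable")) abundances(counts) else
        as.matrix(counts)
    if (any(m != round(m)) || any(m < 0))
        stop("DMM requires non-negative integer counts")
    storage.mode(m) <- "double"
    m
}

#' Fit a Dirichlet multinomial mixture
#'
#' Expectation-maximisation fit of a K-component DMM to genus- (or species-)
#' level counts. The first restart is initialised from k-means on the
#' row-normalised profiles, the remaining restarts from random
#' responsibilities; the best restart by final log-likelihood wins.
#'
#' @param counts \linkS4class{AbundanceTable} or matrix of integer counts
#'   (samples x taxa).
#' @param K number of components (1 <= K <= N).
#' @param seed seed (k-means and random restarts).
#' @param nRestarts restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param alphaPriorRate rate of the vague exponential prior on each
#'   Dirichlet parameter used by the Laplace evidence (default 0.01, i.e.
#'   prior mean 100 — flat over the plausible concentration range; it is the
#'   prior density term that gives the evidence its Occam penalty).
#' @return a \linkS4class{DMMFit}.
#' @examples
#' a <- componentArchetypes()$alpha[, 1:20]
#' set.seed(1)
#' x <- rbind(t(stats::rmultinom(10, 500, a[1, 1:20])),
#'            t(stats::rmultinom(10, 500, a[3, 1:20])))
#' rownames(x) <- paste0("s", 1:20)
#' fit <- fitDMM(x, K = 2, seed = 1, nRestarts = 2)
#' mixtureWeights(fit)
#' @export
fitDMM <- function(counts, K, seed = 1L, nRestarts = 5, tol = 1e-6,
                   maxIter = 500, alphaPriorRate = 0.01) {
    x <- .checkCountMatrix(counts)
    N <- nrow(x)
    K <- as.integer(K)
    if (K < 1) stop("K must be >= 1")
    if (N < K) stop("need at least K samples (N = ", N, ", K = ", K, ")")
    rowTotals <- rowSums(x)
    logCoef <- lgamma(rowTotals + 1) - rowSums(lgamma(x + 1))
    set.seed(seed)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        gamma0 <- if (r == 1 && K > 1) {
            p <- x / rowTotals
            km <- tryCatch(stats::kmeans(p, centers = K, nstart = 3),
                           error = function(e) NULL)
            if (is.null(km)) {
                g <- matrix(stats::rgamma(N * K, 1), N, K)
                g / rowSums(g)
            } else {
                g <- matrix(0.5 / K, N, K)
                g[cbind(seq_len(N), km$cluster)] <-
                    g[cbind(seq_len(N), km$cluster)] + 0.5
                g / rowSums(g)
            }
        } else if (K == 1) {
            matrix(1, N, 1)
        } else {
            g <- matrix(stats::rgamma(N * K, 1), N, K)
            g / rowSums(g)
        }
        run <- .emRun(x, K, gamma0, tol, maxIter, rowTotals, logCoef)
        if (is.null(best) || run$ll > best$ll) best <- run
        if (K == 1) break   # deterministic: restarts are identical
    }
    ev <- .laplaceEvidence(x, best, rowTotals, alphaPriorRate)
    dAll <- K * ncol(x) + K - 1
    bic <- best$ll - dAll / 2 * log(N)
    if (!best$converged)
        warning("EM did not converge in ", maxIter, " iterations (K = ", K,
                ")")
    cn <- colnames(x)
    dimnames(best$alpha) <- list(paste0("comp", seq_len(K)), cn)
    dimnames(best$gamma) <- list(rownames(x), paste0("comp", seq_len(K)))
    new("DMMFit", K = K, weights = as.numeric(best$pi), alpha = best$alpha,
        responsibilities = best$gamma, logLik = best$ll,
        llTrace = best$llTrace, evidence = ev$evidence,
        laplaceOK = ev$laplaceOK, bic = bic,
        converged = best$converged, iterations = best$iter,
        nRestarts = as.integer(nRestarts), seed = as.integer(seed))
}

#' Accessors for DMMFit
#'
#' @param object a \linkS4class{DMMFit}.
#' @return \code{mixtureWeights} the length-K weights; \code{dirichletParams}
#'   the K x J parameter matrix; \code{responsibilities} the N x K posterior
#'   membership matrix; \code{logEvidence} the Laplace log evidence (its BIC
#'   surrogate when the Laplace approximation was unusable — see the
#'   \code{laplaceOK} slot); \code{nComponents} K.
#' @name DMMFit-accessors
#' @aliases mixtureWeights dirichletParams responsibilities logEvidence
#'   nComponents
NULL

#' @rdname DMMFit-accessors
#' @export
setMethod("mixtureWeights", "DMMFit", function(object) object@weights)

#' @rdname DMMFit-accessors
#' @export
setMethod("dirichletParams", "DMMFit", function(object) object@alpha)

#' @rdname DMMFit-accessors
#' @export
setMethod("responsibilities", "DMMFit",
          function(object) object@responsibilities)

#' @rdname DMMFit-accessors
#' @export
setMethod("logEvidence", "DMMFit", function(object) object@evidence)

#' @rdname DMMFit-accessors
#' @export
setMethod("nComponents", "DMMFit", function(object) object@K)

setMethod("show", "DMMFit", function(object) {
    cat(sprintf("DMMFit: K = %d over %d taxa, N = %d samples\n", object@K,
                ncol(object@alpha), nrow(object@responsibilities)))
    cat(sprintf("  logLik %.2f | evidence %.2f | BIC %.2f | %s in %d iter\n",
                object@logLik, logEvidence(object), object@bic,
                if (object@converged) "converged" else "NOT converged",
                object@iterations))
    cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
        "\n")
})

#' Select the number of mixture components
#'
#' Fits every K in \code{kRange} and returns the fit maximising the
#' Laplace-approximate log evidence (per-K BIC fallback when the Hessian
#' blocks are unusable). K values exceeding the sample count are skipped with
#' a warning.
#'
#' @param counts count matrix or \linkS4class{AbundanceTable}.
#' @param kRange candidate K values (default 1..6).
#' @param seed master seed; each K derives its own stream.
#' @param ... passed to \code{\link{fitDMM}}.
#' @return list with \code{bestK}, \code{best} (the winning
#'   \linkS4class{DMMFit}), \code{fits} (all fits, named by K) and
#'   \code{evidence} (named numeric).
#' @export
selectK <- function(counts, kRange = 1:6, seed = 1L, ...) {
    x <- .checkCountMatrix(counts)
    kRange <- as.integer(kRange)
    if (!length(kRange)) stop("kRange must be non-empty")
    drop <- kRange > nrow(x)
    if (any(drop)) {
        warning("skipping K > N: ", paste(kRange[drop], collapse = ", "))
        kRange <- kRange[!drop]
    }
    fits <- lapply(kRange, function(K)
        fitDMM(x, K, seed = stageSeed(seed, paste0("dmmK", K)), ...))
    names(fits) <- kRange
    ev <- vapply(fits, logEvidence, numeric(1))
    bestK <- kRange[which.max(ev)]
    list(bestK = bestK, best = fits[[as.character(bestK)]], fits = fits,
         evidence = ev)
}

#' Assign samples to mixture components
#'
#' Posterior responsibilities of (possibly new) samples under a fitted model;
#' each sample goes to the argmax component.
#'
#' @param model a \linkS4class{DMMFit}.
#' @param counts count matrix or \linkS4class{AbundanceTable} over the same
#'   taxon universe the model was fitted on (same columns, same order after
#'   name matching).
#' @return data.frame with \code{sample_id}, \code{component} (integer),
#'   and \code{responsibility} (posterior probability of that component).
#' @export
assignSamples <- function(model, counts) {
    x <- .checkCountMatrix(counts)
    taxa <- colnames(model@alpha)
    if (is.null(colnames(x)) || !setequal(colnames(x), taxa))
        stop("taxon universe of the counts does not match the fitted model")
    x <- x[, taxa, drop = FALSE]
    rowTotals <- rowSums(x)
    logCoef <- lgamma(rowTotals + 1) - rowSums(lgamma(x + 1))
    logp <- vapply(seq_len(model@K), function(k)
        .dmLogProb(x, model@alpha[k, ], rowTotals, logCoef),
        numeric(nrow(x)))
    logp <- matrix(logp, nrow(x), model@K)
    logpost <- sweep(logp, 2, log(model@weights), `+`)
    gamma <- exp(logpost - .logsumexp(logpost))
    comp <- max.col(gamma, "first")
    data.frame(sample_id = rownames(x), component = comp,
               responsibility = gamma[cbind(seq_len(nrow(x)), comp)],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Label mixture components semantically
#'
#' Maps fitted components to the enterotype names used in the field:
#' the component with the highest expected Faecalibacterium share is Rum; of
#' the rest, the highest expected Bifidobacterium share is Bif; among the
#' remaining Bacteroides-dominated components the one with the lower Shannon
#' diversity of its expected composition is the dysbiotic Bact2, the other
#' Bact1. Components matching no rule become Other_i. A single remaining
#' Bacteroides-dominated component is Bact2 if its expected Shannon diversity
#' is the minimum across all components, otherwise Bact1.
#'
#' @param model a \linkS4class{DMMFit} over genus columns, or over species
#'   columns with \code{taxonomy} supplied.
#' @param taxonomy optional species -> genus map used to collapse expected
#'   compositions to genus level.
#' @param markers names of the marker genera (defaults: Bacteroides,
#'   Faecalibacterium, Bifidobacterium).
#' @return named character vector: component index ("comp1"..) -> label.
#' @export
labelComponents <- function(model, taxonomy = NULL,
                            markers = c(bacteroides = "Bacteroides",
                                        faecalibacterium = "Faecalibacterium",
                                        bifidobacterium = "Bifidobacterium")) {
    alpha <- model@alpha
    m <- alpha / rowSums(alpha)          # expected compositions
    if (!is.null(taxonomy) && length(taxonomy)) {
        orphan <- setdiff(colnames(m), names(taxonomy))
        if (length(orphan) == 0) {
            g <- factor(taxonomy[colnames(m)])
            m <- t(rowsum(t(m), g))
            colnames(m) <- levels(g)
        }
    }
    missing <- setdiff(markers, colnames(m))
    if (length(missing))
        stop("marker genera absent from the fitted taxa: ",
             paste(missing, collapse = ", "))
    K <- nrow(m)
    labels <- stats::setNames(paste0("Other_", seq_len(K)), rownames(alpha))
    ## degenerate tie: all components identical
    if (K > 1 && all(apply(m, 2, function(col) diff(range(col)) < 1e-12))) {
        warning("all components have identical expected compositions; ",
                "labelling is undefined")
        return(labels)
    }
    shan <- apply(m, 1, function(p) {
        p <- p[p > 0]; -sum(p * log(p))
    })
    avail <- seq_len(K)
    rum <- avail[which.max(m[avail, markers[["faecalibacterium"]]])]
    labels[rum] <- "Rum"
    avail <- setdiff(avail, rum)
    if (length(avail)) {
        bif <- avail[which.max(m[avail, markers[["bifidobacterium"]]])]
        labels[bif] <- "Bif"
        avail <- setdiff(avail, bif)
    }
    bactDom <- avail[vapply(avail, function(k)
        colnames(m)[which.max(m[k, ])] == markers[["bacteroides"]],
        logical(1))]
    if (length(bactDom) >= 2) {
        two <- bactDom[order(shan[bactDom])][1:2]
        labels[two[1]] <- "Bact2"
        labels[two[2]] <- "Bact1"
    } else if (length(bactDom) == 1) {
        labels[bactDom] <- if (shan[bactDom] <= min(shan)) "Bact2" else
            "Bact1"
    }
    labels
}

#' Enterotype a cohort in one call
#'
#' Convenience wrapper: fit (or select) a DMM on genus-level counts, label the
#' components, and assign every sample.
#'
#' @param counts genus-level counts (\linkS4class{AbundanceTable} or matrix).
#' @param K fixed number of components, or NULL to select over \code{kRange}.
#' @param kRange candidate orders when \code{K} is NULL.
#' @param seed seed.
#' @param taxonomy optional species -> genus map for labelling.
#' @param ... passed to \code{\link{fitDMM}}.
#' @return list with \code{model}, \code{labels} (component -> semantic
#'   label) and \code{assignments} (data.frame with sample_id, component,
#'   label, responsibility).
#' @export
enterotype <- function(counts, K = NULL, kRange = 1:6, seed = 1L,
                       taxonomy = NULL, ...) {
    model <- if (is.null(K))
        selectK(counts, kRange = kRange, seed = seed, ...)$best
    else fitDMM(counts, K = K, seed = seed, ...)
    labels <- labelComponents(model, taxonomy = taxonomy)
    asg <- assignSamples(model, counts)
    asg$label <- unname(labels[asg$component])
    list(model = model, labels = labels, assignments = asg)
}
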