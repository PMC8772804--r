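## Shared fixtures and independent oracles. Everything is generated in code;
## moderately expensive objects are built once per test run and reused.

## small paired cohort used across modules (~190 samples at depth <= ~4000)
smallCohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- generateCohort(generatorConfig(
                nSubjects = 120, depthMean = 4000, depthDispersion = 50,
                seed = 7))
        cache
    }
})

## a fitted, labelled 4-component model on the small cohort's genus counts
smallEnterotypes <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            coh <- smallCohort()
            rare <- suppressMessages(rarefy(coh$abundanceV1, depth = 2000,
                                            seed = 8))
            genus <- collapseRank(rare)
            cache <<- c(list(rare = rare, genus = genus, cohort = coh),
                        enterotype(genus, K = 4, seed = 9, nRestarts = 2))
        }
        cache
    }
})

## deterministic read-table row
readRow <- function(read_id = "r1", sample_id = "s1", candidate = "A",
                    score = 100, identity = 0.9, aligned = 0.9,
                    human = FALSE) {
    data.frame(read_id = read_id, sample_id = sample_id,
               candidate_taxon = candidate, classifier_score = score,
               confirmed_identity = identity, aligned_fraction = aligned,
               human_flag = human, stringsAsFactors = FALSE)
}

## adjusted Rand index between two labelings (pair-counting oracle)
ari <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    n <- comb2(sum(tab))
    exp0 <- si * sj / n
    (sij - exp0) / ((si + sj) / 2 - exp0)
}

## independent BH step-up oracle (direct formula, no p.adjust)
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        idx <- o[i]
        prev <- min(prev, m * p[idx] / i)
        q[idx] <- min(1, prev)
    }
    q
}

## independent Mann-Whitney U by exhaustive pair counting
uOracle <- function(x, y) {
    sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

## log Dirichlet-multinomial likelihood of a single component (for the
## independent K = 1 oracle based on generic optimisation)
dmLogLik <- function(logAlpha, x) {
    alpha <- exp(logAlpha)
    A <- sum(alpha)
    n <- rowSums(x)
    sum(lgamma(n + 1) - rowSums(lgamma(x + 1)) + lgamma(A) -
            lgamma(A + n) +
            rowSums(lgamma(sweep(x, 2, alpha, `+`))) - sum(lgamma(alpha)))
}
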