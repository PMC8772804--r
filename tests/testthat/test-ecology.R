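test_that("alphaDiversity computes richness and Shannon entropy", {
    m <- rbind(uniform = rep(5L, 8), single = c(40L, rep(0L, 7)),
               mixed = c(5L, 5L, 10L, rep(0L, 4), 20L))
    colnames(m) <- paste0("t", 1:8)
    ## equal depth by construction
    d <- alphaDiversity(abundanceTable(m, depth = 40))
    expect_equal(d$richness, c(8L, 1L, 4L))
    expect_equal(d$shannon[1], log(8))
    expect_equal(d$shannon[2], 0)
    ## direct formula oracle on counts (5, 5, 10)
    p <- c(5, 5, 10) / 20
    expect_equal(alphaDiversity(abundanceTable(
        matrix(c(5, 5, 10), 1, 3,
               dimnames = list("s", c("a", "b", "c"))), depth = 20))$shannon,
        -sum(p * log(p)), tolerance = 1e-12)
    expect_equal(round(-sum(p * log(p)), 4), 1.0397)
    ## unequal depths are refused
    m2 <- rbind(a = c(1L, 2L), b = c(5L, 9L))
    colnames(m2) <- c("x", "y")
    expect_error(alphaDiversity(abundanceTable(m2)), "rarefy")
})

test_that("Shannon entropy is bounded by log richness (evenness in [0,1])", {
    set.seed(1)
    for (i in 1:20) {
        m <- matrix(rpois(40, 10), 4, 10,
                    dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
        m <- t(apply(m, 1, function(r) {        # equalise depths
            as.integer(rmultinom(1, 100, r + 0.5))
        }))
        colnames(m) <- paste0("t", 1:10)
        d <- alphaDiversity(abundanceTable(m, depth = 100))
        expect_true(all(d$shannon <= log(d$richness) + 1e-12))
        ev <- d$evenness[!is.na(d$evenness)]
        expect_true(all(ev >= 0 & ev <= 1))
    }
})

test_that("Bray-Curtis matches the min-overlap formula and its bounds", {
    m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.25, 0.25, 0.5),
               s3 = c(0.5, 0.5, 0), s4 = c(0, 0, 1))
    colnames(m) <- c("A", "B", "C")
    d <- as.matrix(brayCurtis(abundanceTable(m, relative = TRUE)))
    expect_equal(d["s1", "s2"], 0.5)          # 1 - (0.25 + 0.25 + 0)
    expect_equal(d["s1", "s3"], 0)            # identical rows
    expect_equal(d["s1", "s4"], 1)            # disjoint supports
    expect_error(brayCurtis(rbind(a = c(1, 0), b = c(0, 0))), "all-zero")

    set.seed(2)
    r <- matrix(rexp(60), 6, 10, dimnames = list(paste0("s", 1:6),
                                                 paste0("t", 1:10)))
    dr <- as.matrix(brayCurtis(abundanceTable(r)))
    expect_equal(dr, t(dr))
    expect_true(all(diag(dr) == 0))
    expect_true(all(dr >= 0 & dr <= 1 + 1e-12))
    ## independent oracle: vegan on the row-normalised table
    expect_equal(unname(dr),
                 unname(as.matrix(vegan::vegdist(r / rowSums(r)))),
                 tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean configurations exactly", {
    pts <- cbind(x = c(0, 3, 0, 3), y = c(0, 0, 4, 4))
    rownames(pts) <- paste0("s", 1:4)
    p <- pcoa(dist(pts))
    expect_identical(ncol(p$coordinates), 2L)   # planar: 2 positive axes
    expect_equal(as.matrix(dist(p$coordinates)), as.matrix(dist(pts)),
                 tolerance = 1e-9)
    expect_equal(p$negativeMass, 0, tolerance = 1e-9)

    ## identical samples land on coincident coordinates
    m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 1))
    pi2 <- pcoa(dist(m))
    expect_equal(pi2$coordinates["a", ], pi2$coordinates["b", ],
                 tolerance = 1e-9)

    expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA eigenvalue sum equals the Gower-matrix trace", {
    set.seed(3)
    for (i in 1:5) {
        r <- matrix(rexp(50), 5, 10)
        rownames(r) <- paste0("s", 1:5)
        colnames(r) <- paste0("t", 1:10)
        D <- as.matrix(brayCurtis(abundanceTable(r)))
        A <- -0.5 * D^2
        C <- diag(5) - matrix(1 / 5, 5, 5)
        G <- C %*% A %*% C
        expect_equal(sum(pcoa(D)$eigenvalues), sum(diag(G)),
                     tolerance = 1e-9)
    }
})

test_that("dbRDA p-values behave under the null and at the permutation floor", {
    set.seed(4)
    r <- matrix(rexp(300), 30, 10, dimnames = list(paste0("s", 1:30),
                                                   paste0("t", 1:10)))
    d <- brayCurtis(abundanceTable(r))
    ## null covariate: p > 0.05 in >= 90% of seeded trials
    ps <- vapply(1:60, function(s)
        dbrdaUnivariate(d, rnorm(30), nPerm = 99, seed = s)$p, numeric(1))
    expect_gte(mean(ps > 0.05), 0.9)
    ## two planted clusters on disjoint taxon supports: Bray-Curtis 1
    ## across, small within -> p at the permutation floor
    sep <- rbind(cbind(matrix(rexp(50, 1) + 1, 10), matrix(0, 10, 5)),
                 cbind(matrix(0, 10, 5), matrix(rexp(50, 1) + 1, 10)))
    rownames(sep) <- paste0("x", 1:20); colnames(sep) <- paste0("t", 1:10)
    dsep <- brayCurtis(abundanceTable(sep))
    res <- dbrdaUnivariate(dsep, rep(c("a", "b"), each = 10), nPerm = 199,
                           seed = 1)
    expect_equal(res$p, 1 / 200)
    expect_error(dbrdaUnivariate(d, rep(1, 30)), "constant")
})

test_that("dbRDA ranks a stronger planted gradient above a weaker one", {
    ok <- vapply(1:30, function(s) {
        set.seed(s)
        g1 <- rnorm(24)                     # strong driver
        g2 <- rnorm(24)                     # weak driver
        base <- matrix(rexp(24 * 8), 24, 8)
        m <- base * exp(outer(g1, rep(c(2, -2), 4)) +
                            outer(g2, rep(c(0.3, -0.3), 4)))
        rownames(m) <- paste0("s", 1:24); colnames(m) <- paste0("t", 1:8)
        d <- brayCurtis(abundanceTable(m))
        r1 <- dbrdaUnivariate(d, g1, nPerm = 19, seed = s)$R2
        r2 <- dbrdaUnivariate(d, g2, nPerm = 19, seed = s)$R2
        r1 > r2
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("stepwise dbRDA eliminates redundancy and finds planted drivers", {
    set.seed(5)
    g <- rnorm(30)
    base <- matrix(rexp(30 * 8), 30, 8)
    m <- base * exp(outer(g, rep(c(2, -2), 4)))
    rownames(m) <- paste0("s", 1:30); colnames(m) <- paste0("t", 1:8)
    d <- brayCurtis(abundanceTable(m))
    ## exact duplicates: exactly one of the pair selected
    cov2 <- data.frame(a = g, b = g)
    sel <- dbrdaStepwise(d, cov2, nPerm = 99, seed = 1)
    expect_identical(nrow(sel), 1L)
    expect_true(sel$covariate %in% c("a", "b"))
    ## planted driver beats noise candidates
    ## the scope (full-model) adjusted-R2 rule needs companions with real,
    ## weaker effects; against pure-noise scopes it can refuse all terms,
    ## exactly like the reference stepwise-ordination implementation
    set.seed(99)
    n2 <- 60
    g1 <- rnorm(n2); w1 <- rnorm(n2); w2 <- rnorm(n2)
    base2 <- matrix(rexp(n2 * 8), n2, 8)
    m2 <- base2 * exp(outer(g1, rep(c(1.5, -1.5), 4)) +
                          outer(w1, rep(c(0.4, -0.4), 4)) +
                          outer(w2, rep(c(-0.4, 0.4), 4)))
    rownames(m2) <- paste0("s", 1:n2); colnames(m2) <- paste0("t", 1:8)
    d2 <- brayCurtis(abundanceTable(m2))
    firsts <- vapply(1:10, function(s) {
        set.seed(100 + s)
        covs <- data.frame(driver = g1, w1 = w1, w2 = w2,
                           n1 = rnorm(n2), n2 = rnorm(n2))
        sel <- dbrdaStepwise(d2, covs, nPerm = 99, seed = s)
        if (nrow(sel)) sel$covariate[1] else "none"
    }, character(1))
    expect_gte(mean(firsts == "driver"), 0.95)
    ## all-noise candidates against an unstructured community
    set.seed(6)
    noise <- as.data.frame(matrix(rnorm(30 * 6), 30, 6))
    dNoise <- dist(matrix(rnorm(60), 30, 2))
    selN <- dbrdaStepwise(dNoise, noise, nPerm = 99, seed = 2)
    expect_lte(nrow(selN), 1L)
})

test_that("PERMANOVA matches exhaustive enumeration at n = 6", {
    set.seed(7)
    pts <- matrix(rnorm(12), 6, 2)
    rownames(pts) <- paste0("s", 1:6)
    d <- dist(pts)
    grp <- rep(c("a", "b"), each = 3)
    res <- permanova(d, grp, nPerm = 9999, seed = 1)
    ## brute force: enumerate all 6! label orderings
    d2 <- as.matrix(d)^2
    Fstat <- function(g) {
        sst <- sum(d2[lower.tri(d2)]) / 6
        ssw <- sum(vapply(unique(g), function(x) {
            i <- which(g == x)
            sum(d2[i, i][lower.tri(d2[i, i])]) / length(i)
        }, numeric(1)))
        ((sst - ssw) / 1) / (ssw / 4)
    }
    perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6), ]
    Fobs <- Fstat(grp)
    Fall <- apply(perms, 1, function(ix) Fstat(grp[ix]))
    pExact <- mean(Fall >= Fobs - 1e-12)
    expect_lt(abs(res$p - pExact), 0.02)
    expect_error(permanova(d, rep("a", 6)), "constant")
})

test_that("PERMANOVA hits the permutation floor for separated clusters", {
    set.seed(8)
    pts <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 5, 0.2), 10))
    res <- permanova(dist(pts), rep(c("a", "b"), each = 10), nPerm = 999,
                     seed = 1)
    expect_equal(res$p, 0.001)
    expect_warning(
        permanova(dist(pts), rep(c("a", "b"), each = 10),
                  strata = c("z", rep(c("u", "v"), c(9, 10))),
                  nPerm = 19, seed = 1),
        "single sample")
})

test_that("dbRDA and PERMANOVA agree on R2 for one covariate (Euclidean D)", {
    set.seed(9)
    pts <- matrix(rnorm(40), 20, 2)
    rownames(pts) <- paste0("s", 1:20)
    d <- dist(pts)
    grp <- rep(c("a", "b"), each = 10)
    r1 <- dbrdaUnivariate(d, grp, nPerm = 19, seed = 1)$R2
    r2 <- permanova(d, grp, nPerm = 19, seed = 1)$R2
    expect_equal(r1, r2, tolerance = 1e-9)
    ## and with the reference implementation
    r3 <- vegan::adonis2(d ~ grp, permutations = 19)
    expect_equal(r1, r3$R2[1], tolerance = 1e-9)
})

test_that("null permutation p-values are uniform on the achievable grid", {
    set.seed(10)
    pts <- matrix(rnorm(40), 20, 2)
    rownames(pts) <- paste0("s", 1:20)
    d <- dist(pts)
    ps <- vapply(1:500, function(s) {
        g <- sample(rep(c("a", "b"), each = 10))
        permanova(d, g, nPerm = 49, seed = 1000 + s)$p
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})
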