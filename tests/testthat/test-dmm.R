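test_that("K = 1 fit matches an independent optimiser to 1e-6 relative", {
    set.seed(1)
    alpha <- c(8, 4, 2, 1)
    x <- t(vapply(1:60, function(i) sampleComposition(alpha, 300),
                  integer(4)))
    colnames(x) <- paste0("t", 1:4)
    rownames(x) <- paste0("s", 1:60)
    fit <- fitDMM(x, K = 1, seed = 1, tol = 1e-16, maxIter = 20000)
    ## oracle: generic quasi-Newton optimisation of the DM likelihood in
    ## log space, independent of the EM fixed-point path
    dmGrad <- function(logAlpha, x) {
        alpha <- exp(logAlpha)
        A <- sum(alpha)
        n <- rowSums(x)
        N <- nrow(x)
        alpha * (N * digamma(A) - sum(digamma(A + n)) +
                     colSums(digamma(sweep(x, 2, alpha, `+`))) -
                     N * digamma(alpha))
    }
    ## box constraints keep the optimiser out of the numerically degenerate
    ## huge-alpha region (catastrophic lgamma cancellation), far from the MLE
    opt <- optim(log(colMeans(x / rowSums(x)) * 10), dmLogLik, dmGrad,
                 x = x, method = "L-BFGS-B", lower = -10, upper = 12,
                 control = list(fnscale = -1, factr = 10, maxit = 2000))
    expect_equal(unname(dirichletParams(fit)[1, ]), unname(exp(opt$par)),
                 tolerance = 1e-6)
    expect_equal(logLik <- fit@logLik, opt$value, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone non-decreasing", {
    et <- smallEnterotypes()
    tr <- et$model@llTrace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-1])))
    ## also from a purely random start
    set.seed(2)
    x <- matrix(rpois(200, 30), 20, 10,
                dimnames = list(paste0("s", 1:20), paste0("t", 1:10)))
    f <- suppressWarnings(fitDMM(x, K = 3, seed = 3, nRestarts = 1,
                                 maxIter = 60))
    expect_true(all(diff(f@llTrace) >= -1e-8 * abs(f@llTrace[-1])))
})

test_that("well-separated components are recovered (ARI >= 0.95)", {
    arch <- componentArchetypes(concentrations = c(Bact1 = 50, Bact2 = 50,
                                                   Rum = 50, Bif = 50))
    genusAlpha <- t(rowsum(t(arch$alpha), factor(arch$taxonomy)))
    set.seed(4)
    truth <- sample(c("Bact1", "Rum"), 200, replace = TRUE)
    x <- t(vapply(truth, function(k)
        sampleComposition(genusAlpha[k, ], 1000), integer(ncol(genusAlpha))))
    rownames(x) <- paste0("s", 1:200)
    fit <- fitDMM(x, K = 2, seed = 5, nRestarts = 3)
    hard <- max.col(responsibilities(fit))
    expect_gte(ari(hard, truth), 0.95)
    ## responsibilities and weights live on their simplices
    expect_equal(unname(rowSums(responsibilities(fit))), rep(1, 200),
                 tolerance = 1e-9)
    expect_equal(sum(mixtureWeights(fit)), 1, tolerance = 1e-9)
})

test_that("fitDMM validates its inputs", {
    x <- matrix(1.5, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
    expect_error(fitDMM(x, 1), "integer")
    xi <- matrix(1L, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
    expect_error(fitDMM(xi, 5), "at least K samples")
})

test_that("selectK maximises evidence and recovers the null order", {
    et <- smallEnterotypes()
    genus <- et$genus
    sel <- suppressWarnings(selectK(genus, c(3, 4), seed = 6,
                                    nRestarts = 2))
    expect_identical(unname(sel$evidence[as.character(sel$bestK)]),
                     max(sel$evidence))
    ## single-component data selects K = 1
    arch <- componentArchetypes()
    set.seed(7)
    x <- t(vapply(1:80, function(i)
        sampleComposition(arch$alpha["Rum", ], 3000),
        integer(ncol(arch$alpha))))
    rownames(x) <- paste0("s", 1:80)
    gx <- t(rowsum(t(x), factor(arch$taxonomy[colnames(x)])))
    sel1 <- suppressWarnings(selectK(gx, 1:3, seed = 8, nRestarts = 2))
    expect_identical(sel1$bestK, 1L)
    expect_warning(selectK(gx[1:4, ], c(2, 10), seed = 1, nRestarts = 1),
                   "K > N")
    ## evidence- and BIC-based selection agree on well-separated fixtures
    ## (disagreements are logged, not failed)
    bicBest <- as.integer(names(which.max(vapply(sel$fits, function(f)
        f@bic, numeric(1)))))
    if (bicBest != sel$bestK)
        message("evidence/BIC selection disagreement: ", sel$bestK, " vs ",
                bicBest)
    expect_true(is.finite(sel$evidence[[as.character(sel$bestK)]]))
})

test_that("species-level enterotyping labels via the taxonomy map", {
    et <- smallEnterotypes()
    species <- et$rare   # species-level rarefied counts
    fit <- suppressWarnings(fitDMM(species, K = 4, seed = 11,
                                   nRestarts = 1, maxIter = 150))
    labels <- labelComponents(fit, taxonomy = taxonomyMap(species))
    expect_setequal(unname(labels), c("Bact1", "Bact2", "Rum", "Bif"))
})

test_that("assignSamples is self-consistent, order-invariant and checked", {
    et <- smallEnterotypes()
    model <- et$model
    genus <- abundances(et$genus)
    asg <- assignSamples(model, genus)
    ## permuting sample order permutes assignments identically
    perm <- sample(nrow(genus))
    asgP <- assignSamples(model, genus[perm, ])
    expect_identical(asgP$component[match(asg$sample_id, asgP$sample_id)],
                     asg$component)
    ## duplicate rows receive identical assignments
    dup <- genus[c(1, 1), ]
    rownames(dup) <- c("d1", "d2")
    asgD <- assignSamples(model, dup)
    expect_identical(asgD$component[1], asgD$component[2])
    ## a sharp draw from a fitted component is assigned to it
    k <- 1L
    aK <- dirichletParams(model)[k, ]
    sharp <- matrix(sampleComposition(aK * 50, 5000, seed = 9), 1,
                    dimnames = list("sharp", names(aK)))
    expect_identical(assignSamples(model, sharp)$component, k)
    expect_error(assignSamples(model, genus[, 1:3]), "universe")
})

test_that("components are labelled by the marker-genus rules", {
    et <- smallEnterotypes()
    labels <- et$labels
    expect_setequal(unname(labels), c("Bact1", "Bact2", "Rum", "Bif"))
    ## labels agree with the generator truth channel
    truth <- et$cohort$truth$componentV1
    asg <- et$assignments
    subj <- sub("_V1$", "", asg$sample_id)
    agree <- mean(asg$label == truth[subj])
    expect_gte(agree, 0.9)
    ## the dysbiotic component has the lowest expected Shannon diversity
    m <- dirichletParams(et$model)
    m <- m / rowSums(m)
    shan <- apply(m, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
    expect_identical(names(which(labels == "Bact2")),
                     names(which.min(shan)))
})

test_that("degenerate labelling falls back to Other with a warning", {
    a <- matrix(1, 3, 4, dimnames = list(paste0("comp", 1:3),
                                         c("Bacteroides", "Faecalibacterium",
                                           "Bifidobacterium", "Blautia")))
    g <- matrix(1 / 3, 2, 3)
    model <- new("DMMFit", K = 3L, weights = rep(1 / 3, 3), alpha = a,
                 responsibilities = g, logLik = 0, llTrace = 0,
                 evidence = 0, laplaceOK = TRUE, bic = 0, converged = TRUE,
                 iterations = 1L, nRestarts = 1L, seed = 1L)
    expect_warning(lab <- labelComponents(model), "identical")
    expect_true(all(grepl("^Other_", lab)))
    a2 <- a; colnames(a2)[1] <- "NotBacteroides"
    model@alpha <- a2
    expect_error(suppressWarnings(labelComponents(model)), "Bacteroides")
})

test_that("held-out samples map to their true components", {
    et <- smallEnterotypes()
    arch <- componentArchetypes()
    genusAlpha <- t(rowsum(t(arch$alpha), factor(arch$taxonomy)))
    set.seed(10)
    truth <- sample(rownames(genusAlpha), 80, replace = TRUE)
    held <- t(vapply(truth, function(k)
        sampleComposition(genusAlpha[k, ], 2000),
        integer(ncol(genusAlpha))))
    rownames(held) <- paste0("h", 1:80)
    held <- held[, colnames(dirichletParams(et$model))]
    asg <- assignSamples(et$model, held)
    pred <- unname(et$labels[asg$component])
    expect_gte(mean(pred == truth), 0.9)
})
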