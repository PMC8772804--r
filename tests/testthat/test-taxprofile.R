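test_that("confirmAssignments applies thresholds and removes human reads", {
    r <- rbind(readRow("r1", identity = 0.30),
               readRow("r2", identity = 0.95, human = TRUE),
               readRow("r3", identity = 0.95, aligned = 0.2),
               readRow("r4", identity = 0.95, aligned = 0.9))
    out <- confirmAssignments(r)
    expect_identical(out$read_id, "r4")
    ## idempotence: applying twice equals once
    expect_identical(confirmAssignments(out), out)
    expect_warning(confirmAssignments(r[0, ]), "empty")
    expect_error(confirmAssignments(r, minIdentity = 1.2), "\\[0, 1\\]")
    expect_error(confirmAssignments(r[, -5]), "confirmed_identity")
})

test_that("the two-step filter separates planted false positives", {
    m <- matrix(c(4000, 3000, 3000), 1, 3,
                dimnames = list("s1", c("A", "B", "C")))
    ra <- generateReadAssignments(m, readsPerSample = 20000,
                                  falsePositiveRate = 0.1, seed = 11)
    kept <- confirmAssignments(ra$reads)
    isFP <- stats::setNames(ra$truth$false_positive, ra$truth$read_id)
    fpKept <- sum(isFP[kept$read_id])
    fpAll <- sum(isFP)
    trueAll <- sum(!isFP & !ra$reads$human_flag)
    trueKept <- sum(!isFP[kept$read_id])
    expect_gte((fpAll - fpKept) / fpAll, 0.95)   # >= 95% of FPs removed
    expect_gte(trueKept / trueAll, 0.95)         # <= 5% of true reads lost
    expect_false(any(kept$human_flag))
})

test_that("collapseCandidates keeps the top-score candidate, ties by taxon", {
    r <- rbind(readRow("r1", candidate = "B", score = 5),
               readRow("r1", candidate = "A", score = 5),
               readRow("r1", candidate = "C", score = 9),
               readRow("r2", candidate = "Z", score = 1))
    out <- collapseCandidates(r)
    expect_identical(out$candidate_taxon[out$read_id == "r1"], "C")
    r2 <- r[r$classifier_score == 5, ]
    expect_identical(collapseCandidates(r2)$candidate_taxon, "A")
})

test_that("tabulateReads counts reads per sample and species", {
    r <- rbind(readRow(paste0("r", 1:5), "s1", "A"),
               readRow(paste0("q", 1:3), "s1", "B"),
               readRow(paste0("p", 1:2), "s2", "C"))
    at <- tabulateReads(r)
    expect_equal(abundances(at)["s1", c("A", "B")], c(A = 5, B = 3))
    ## samples sharing no species: zeros off-block
    expect_equal(abundances(at)["s2", c("A", "B")], c(A = 0, B = 0))
    expect_equal(abundances(at)["s1", "C"], 0)
    ## oracle equality with an independent group-by
    oracle <- tapply(rep(1, nrow(r)), list(r$sample_id, r$candidate_taxon),
                     sum)
    oracle[is.na(oracle)] <- 0
    expect_equal(unname(abundances(at)[rownames(oracle), colnames(oracle)]),
                 unname(oracle))
    expect_identical(dim(tabulateReads(r[0, ])), c(0L, 0L))
})

test_that("rarefy subsamples to exact depth and excludes shallow samples", {
    set.seed(1)
    m <- rbind(s1 = as.integer(rmultinom(1, 50000, c(0.6, 0.3, 0.1))),
               s2 = as.integer(rmultinom(1, 9999, c(0.3, 0.3, 0.4))),
               s3 = as.integer(rmultinom(1, 12000, c(0.2, 0.2, 0.6))))
    colnames(m) <- c("A", "B", "C")
    at <- abundanceTable(m)
    expect_message(out <- rarefy(at, depth = 10000, seed = 2), "s2")
    expect_identical(attr(out, "excluded"), "s2")
    expect_true(all(rowSums(abundances(out)) == 10000))
    expect_equal(rarefiedDepth(out), 10000)
    expect_error(suppressMessages(rarefy(at, depth = 1e6, seed = 1)),
                 "no sample")
    expect_error(rarefy(abundanceTable(m / 3), 10), "integer")
})

test_that("rarefaction preserves expected proportions (hypergeometric mean)", {
    m <- matrix(c(600, 300, 100), 1, 3,
                dimnames = list("s1", c("A", "B", "C")))
    at <- abundanceTable(m)
    props <- t(vapply(1:400, function(s)
        abundances(rarefy(at, depth = 100, seed = s))[1, ] / 100,
        numeric(3)))
    target <- c(0.6, 0.3, 0.1)
    se <- apply(props, 2, sd) / sqrt(nrow(props))
    expect_true(all(abs(colMeans(props) - target) < 3 * se))
})

test_that("rarefy agrees with the standard community-ecology subsampler", {
    ## same exact-depth contract and marginal behaviour as vegan::rrarefy
    set.seed(3)
    m <- matrix(rpois(30, 400), 3, 10,
                dimnames = list(paste0("s", 1:3), paste0("t", 1:10)))
    ours <- abundances(rarefy(abundanceTable(m), depth = 500, seed = 4))
    set.seed(4)
    theirs <- suppressWarnings(vegan::rrarefy(m, 500))
    expect_true(all(rowSums(ours) == 500) && all(rowSums(theirs) == 500))
    expect_true(all(ours <= m) && all(theirs <= m))
})

test_that("collapseRank sums within genus and conserves totals", {
    m <- matrix(c(4, 1, 6, 2, 3, 5), 2, 3,
                dimnames = list(c("s1", "s2"), c("g1_a", "g1_b", "g2_a")))
    tax <- c(g1_a = "g1", g1_b = "g1", g2_a = "g2")
    at <- abundanceTable(m, taxonomy = tax)
    g <- collapseRank(at)
    expect_equal(abundances(g)["s1", "g1"], 10)
    expect_equal(rowSums(abundances(g)), rowSums(m))
    ## identity on an already-genus table
    expect_identical(collapseRank(g), g)
    expect_error(collapseRank(abundanceTable(m, taxonomy = tax[-1])),
                 "g1_a")
})

test_that("collapseRank conserves totals on a random fixture", {
    coh <- smallCohort()
    g <- collapseRank(coh$abundanceV1)
    expect_equal(rowSums(abundances(g)),
                 rowSums(abundances(coh$abundanceV1)))
})

test_that("filterFeatures applies the >= abundance in >= prevalence rule", {
    ## feature at exactly 5e-4 in exactly 20% of samples is kept
    m <- matrix(1e-5, 10, 3, dimnames = list(paste0("s", 1:10),
                                             c("keep", "drop", "zero")))
    m[1:2, "keep"] <- 5e-4
    m[1, "drop"] <- 0.10
    m[, "zero"] <- 0
    ## pad with a filler feature so rows sum to 1 without rescaling the rest
    at <- abundanceTable(cbind(m, rest = 1 - rowSums(m)), relative = TRUE)
    out <- filterFeatures(at, minAbund = 5e-4, minPrev = 0.20)
    expect_true("keep" %in% taxonIDs(out))
    expect_false("drop" %in% taxonIDs(out))    # 10% prevalence < 20%
    expect_false("zero" %in% taxonIDs(out))
    expect_identical(sort(attr(out, "removed")), c("drop", "zero"))
    expect_error(filterFeatures(abundanceTable(m)), "relative")
})
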