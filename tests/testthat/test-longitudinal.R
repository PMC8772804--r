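test_that("median stratification splits at the reference median", {
    r <- setNames(1:10, paste0("s", 1:10))
    s <- stratifyByMedian(r)
    expect_equal(attr(s, "threshold"), 5.5)
    expect_identical(names(s)[s == "low"], paste0("s", 1:5))
    expect_identical(names(s)[s == "high"], paste0("s", 6:10))
    ## threshold from a wider reference set, applied to a subset
    s2 <- stratifyByMedian(r[1:4], reference = r)
    expect_true(all(s2 == "low"))
    expect_warning(stratifyByMedian(setNames(rep(3, 4), letters[1:4])),
                   "all")
    expect_error(stratifyByMedian(r, reference = numeric(0)), "empty")
})

test_that("low-concentration subjects land in the low-diversity stratum", {
    et <- smallEnterotypes()
    div <- alphaDiversity(et$rare)
    rich <- setNames(div$richness, sub("_V1$", "", div$sample_id))
    s <- stratifyByMedian(rich)
    truth <- et$cohort$truth$componentV1[names(rich)]
    ## Bact2 has much the lowest total concentration -> lowest richness
    expect_gte(mean(s[truth == "Bact2"] == "low"), 0.8)
})

test_that("fold-change comparison handles identity and zero baselines", {
    v1 <- setNames(c(10, 20, 30, 40), paste0("s", 1:4))
    strata <- setNames(factor(c("low", "low", "high", "high"),
                              c("low", "high")), names(v1))
    res <- compareFoldChanges(v1, v1, strata)
    expect_true(all(res$foldChanges$fc == 1))
    v1z <- v1; v1z["s1"] <- 0
    expect_message(res2 <- compareFoldChanges(v1z, v1, strata), "s1")
    expect_identical(res2$excluded, "s1")
    expect_false("s1" %in% res2$foldChanges$subject)
})

test_that("rank-sum statistic agrees with exhaustive U counting", {
    v1 <- setNames(rep(1, 12), paste0("s", 1:12))
    v2 <- setNames(c(1.9, 1.2, 1.6, 1.1, 1.4, 1.3,
                     0.8, 1.05, 0.9, 1.15, 0.95, 1.0), names(v1))
    strata <- setNames(factor(rep(c("low", "high"), each = 6),
                              c("low", "high")), names(v1))
    res <- compareFoldChanges(v1, v2, strata)
    fc <- res$foldChanges
    w <- suppressWarnings(wilcox.test(fc$fc[fc$stratum == "low"],
                                      fc$fc[fc$stratum == "high"]))
    expect_equal(res$betweenP, w$p.value)
    expect_equal(unname(w$statistic),
                 uOracle(fc$fc[fc$stratum == "low"],
                         fc$fc[fc$stratum == "high"]))
})

test_that("planted low-stratum improvement is detected at n = 80", {
    hits <- 0; reps <- 30
    for (r in 1:reps) {
        set.seed(700 + r)
        n <- 80
        strata <- setNames(factor(rep(c("low", "high"), each = n / 2),
                                  c("low", "high")), paste0("s", 1:n))
        v1 <- setNames(rexp(n, 1 / 100) + 50, names(strata))
        lfc <- rnorm(n, ifelse(strata == "low", 0.25, 0), 0.3)
        v2 <- v1 * exp(lfc)
        res <- compareFoldChanges(v1, v2, strata)
        hits <- hits + (res$betweenP < 0.05)
    }
    expect_gte(hits / reps, 0.9)
})

test_that("between-stratum fold-change test holds its type-I error", {
    rej <- vapply(1:1000, function(s) {
        set.seed(3000 + s)
        fcLow <- exp(rnorm(40, 0, 0.3))
        fcHigh <- exp(rnorm(40, 0, 0.3))
        suppressWarnings(wilcox.test(fcLow, fcHigh)$p.value) < 0.05
    }, logical(1))
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
})

test_that("transition test reports switch fractions and chi-square", {
    ## identity: zero statistic, p = 1
    v1 <- setNames(rep(c("Bact1", "Bact2"), each = 5), paste0("s", 1:10))
    res <- transitionTest(v1, v1)
    expect_equal(res$statistic, 0)
    expect_equal(res$p, 1)

    ## printed-counts fixture: 36 baseline Bact2, 16 -> Bact1, 14 stay
    from <- rep("Bact2", 36)
    to <- rep(c("Bact1", "Bact2", "Rum", "Bif"), c(16, 14, 3, 3))
    extra <- rep(c("Bact1", "Rum"), c(30, 23))
    v1b <- setNames(c(from, extra), paste0("p", 1:89))
    v2b <- setNames(c(to, extra), paste0("p", 1:89))
    resB <- transitionTest(v1b, v2b)
    sw <- resB$switches
    expect_equal(sw$percent[sw$from == "Bact2" & sw$to == "Bact1"], 44)
    expect_equal(sw$percent[sw$from == "Bact2" & sw$to == "Bact2"], 39)
    expect_equal(sw$denom[sw$from == "Bact2" & sw$to == "Bact1"], 36L)

    ## chi-square matches the hand-computed 2 x K statistic
    marg <- resB$marginals
    expected <- outer(rowSums(marg), colSums(marg)) / sum(marg)
    expect_equal(resB$statistic, sum((marg - expected)^2 / expected),
                 tolerance = 1e-12)
    expect_error(transitionTest(v1b[1], v2b[1]), ">= 2")
    ## Stuart-Maxwell option runs on the paired table
    resSM <- transitionTest(v1b, v2b, method = "stuart-maxwell")
    expect_true(resSM$statistic > 0 && resSM$p < 1)
})

test_that("LMM with zero subject variance matches OLS and recovers 0.03", {
    set.seed(6)
    n <- 100
    subject <- rep(paste0("s", 1:n), 2)
    visit <- rep(c("V1", "V2"), each = n)
    y <- 0.1 + 0.03 * (visit == "V2") + rnorm(2 * n, 0, 0.05)
    r <- lmmFeature(y, visit, subject)
    ols <- summary(lm(y ~ visit))$coefficients
    expect_equal(r$beta, ols[2, 1], tolerance = 1e-6)
    expect_true(abs(r$beta - 0.03) <= qnorm(0.975) * r$se)
    expect_true(r$var_subject >= 0 && r$var_residual >= 0)
})

test_that("balanced paired LMM Wald z^2 approximates the paired t^2", {
    set.seed(7)
    n <- 100
    subjEff <- rnorm(n, 0, 0.3)
    y1 <- 1 + subjEff + rnorm(n, 0, 0.1)
    y2 <- 1.15 + subjEff + rnorm(n, 0, 0.1)
    r <- lmmFeature(c(y1, y2), rep(c("V1", "V2"), each = n),
                    rep(paste0("s", 1:n), 2))
    tt <- t.test(y2, y1, paired = TRUE)
    z2 <- (r$beta / r$se)^2
    expect_lt(abs(z2 / tt$statistic^2 - 1), 0.05)
})

test_that("LMM flags degenerate features and drops single-level LMP", {
    n <- 10
    visit <- rep(c("V1", "V2"), each = n)
    subject <- rep(paste0("s", 1:n), 2)
    r <- lmmFeature(rep(2, 2 * n), visit, subject)
    expect_true(r$degenerate)
    expect_equal(r$beta, 0)
    set.seed(8)
    y <- rnorm(2 * n)
    expect_message(lmmFeature(y, visit, subject, lmp = rep(TRUE, 2 * n)),
                   "LMP")
    r2 <- lmmFeature(y, visit, subject,
                     lmp = rep(rep(c(TRUE, FALSE), each = n / 2), 2))
    expect_false(is.na(r2$var_lmp))
    expect_error(lmmFeature(y[1:3], rep("V1", 3), subject[1:3]), "2 levels")
})

test_that("lmmFeatures applies BH across the family", {
    set.seed(9)
    n <- 30
    visit <- rep(c("V1", "V2"), each = n)
    subject <- rep(paste0("s", 1:n), 2)
    f <- cbind(sig = 0.2 * (visit == "V2") + rnorm(2 * n, 0, 0.1),
               null = rnorm(2 * n))
    rownames(f) <- paste0("r", seq_len(2 * n))
    res <- lmmFeatures(f, visit, subject)
    expect_equal(res$q, bhAdjust(res$p))
    expect_lt(res$q[res$feature == "sig"], 0.05)
})

test_that("paired clinical summary reproduces the paired t and stars", {
    set.seed(10)
    n <- 163
    w1 <- rnorm(n, 90.5, 16.3)
    clin <- data.frame(subject_id = rep(paste0("s", 1:n), 2),
                       visit = rep(c("V1", "V2"), each = n),
                       weight = c(w1, 0.9 * w1 + rnorm(n, 0, 2)),
                       flat = rep(rnorm(n), 2))
    res <- pairedClinical(clin)
    wRow <- res[res$variable == "weight", ]
    expect_identical(wRow$stars, "****")
    fRow <- res[res$variable == "flat", ]
    expect_identical(fRow$stars, "ns")
    expect_equal(fRow$t, 0)
    ## paired t equals the one-sample t on differences
    tt <- t.test(clin$weight[clin$visit == "V2"] -
                     clin$weight[clin$visit == "V1"])
    expect_equal(wRow$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(wRow$p, tt$p.value, tolerance = 1e-12)
})

test_that("a planted weight drop at Table-1 spread is always detected", {
    hits <- 0; reps <- 30
    for (r in 1:reps) {
        set.seed(1100 + r)
        n <- 163
        w1 <- rnorm(n, 90.5, 16.3)
        w2 <- 0.9 * w1 + rnorm(n, 0, 3)
        p <- t.test(w2, w1, paired = TRUE)$p.value
        hits <- hits + (p <= 1e-4)
    }
    expect_gte(hits / reps, 0.99)
})
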