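test_that("methylation dichotomization uses the inclusive cutoff", {
    expect_identical(classifyMethylation(8.0), "methylated")
    expect_identical(classifyMethylation(7.9), "unmethylated")
    expect_identical(classifyMethylation(37.0), "methylated")
    expect_identical(classifyMethylation(NA_real_), NA_character_)
    expect_error(classifyMethylation(105), "out of")
    # monotone in pct
    pct <- seq(0, 100, by = 0.5)
    st <- classifyMethylation(pct)
    expect_true(all(diff(st == "methylated") >= 0))
})

test_that("median split sends ties to the low group", {
    sp <- medianSplit(c(10, 20, 30, 40))
    expect_equal(sp$cutoff, 25)
    expect_equal(sort(sp$high), c(30, 40))
    expect_equal(sort(sp$low), c(10, 20))

    sp2 <- medianSplit(c(10, 37, 60))
    expect_equal(sp2$cutoff, 37)
    expect_equal(sp2$high, 60)
    expect_equal(sort(sp2$low), c(10, 37))
    expect_equal(sp2$nTies, 1)

    expect_warning(sp3 <- medianSplit(c(5, 5, 5)), "degenerate")
    expect_length(sp3$high, 0)
})

test_that("2x2 chi-square matches the hand formula and is uncorrected", {
    # independent single-pass oracle: sum (O - E)^2 / E over the four cells
    chisqOracle <- function(tab) {
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        sum((tab - E)^2 / E)
    }
    set.seed(42)
    for (i in 1:20) {
        tab <- matrix(rpois(4, 20) + 1, 2)
        res <- chiSquare2x2(tab)
        expect_equal(res$statistic, chisqOracle(tab), tolerance = 1e-12)
        expect_equal(res$p_value, pchisq(chisqOracle(tab), 1, lower.tail = FALSE))
        # invariance under simultaneous row and column swaps
        res2 <- chiSquare2x2(tab[2:1, 2:1])
        expect_equal(res2$statistic, res$statistic)
    }
    even <- chiSquare2x2(matrix(10, 2, 2))
    expect_equal(even$statistic, 0)
    expect_equal(even$p_value, 1)
    expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("pooled t-test matches the textbook formula and is antisymmetric", {
    res <- twoSampleT(c(1, 2, 3), c(4, 5, 6))
    expect_equal(abs(res$statistic), 3.674, tolerance = 5e-4)
    sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4
    tOracle <- (mean(c(1, 2, 3)) - mean(c(4, 5, 6))) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(res$statistic, tOracle, tolerance = 1e-12)

    swapped <- twoSampleT(c(4, 5, 6), c(1, 2, 3))
    expect_equal(swapped$statistic, -res$statistic)
    expect_equal(swapped$p_value, res$p_value)

    same <- twoSampleT(c(2, 2), c(2, 2))
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)
    expect_error(twoSampleT(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("Pearson correlation matches the sum formula", {
    expect_equal(pearsonR(1:10, 2 * (1:10) + 1)$statistic, 1.0)
    expect_equal(pearsonR(1:10, -(1:10))$statistic, -1.0)
    set.seed(7)
    x <- rnorm(30); y <- rnorm(30)
    rOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearsonR(x, y)$statistic, rOracle, tolerance = 1e-12)
    expect_error(pearsonR(rep(1, 5), 1:5), "constant")
})

test_that("partial correlation equals the residual correlation", {
    set.seed(13)
    for (i in 1:25) {
        n <- sample(10:60, 1)
        z <- rnorm(n)
        x <- 0.5 * z + rnorm(n)
        y <- -0.3 * z + rnorm(n)
        got <- partialR(x, y, z)
        oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
        expect_equal(got$statistic, oracle, tolerance = 1e-10)
        expect_equal(got$df1, n - 3)
    }
    # z orthogonal to both x and y reduces to the plain correlation
    x <- c(1, 2, 3, 4, 2, 5); y <- c(2, 1, 4, 3, 5, 4)
    z0 <- resid(lm(rnorm(6) ~ x + y))
    expect_equal(partialR(x, y, z0)$statistic, cor(x, y), tolerance = 1e-10)
    expect_error(partialR(x, y, x), "collinear")
})

test_that("Wilks repeated-measures F reduces to the paired t at k = 2", {
    set.seed(3)
    M <- cbind(rnorm(15, 1), rnorm(15))
    res <- rmAnovaWilks(M)
    tPaired <- t.test(M[, 1], M[, 2], paired = TRUE)$statistic
    expect_equal(res$statistic, unname(tPaired^2), tolerance = 1e-10)
    expect_equal(c(res$df1, res$df2), c(1, 14))
})

test_that("Wilks lambda matches the multivariate linear model machinery", {
    set.seed(8)
    n <- 25; k <- 5
    M <- matrix(rnorm(n * k), n) + matrix(rep(c(0, 0.4, 0.8, 0.2, 0), each = n), n)
    z <- rnorm(n)
    Y <- M %*% gbmtopo:::.diffContrasts(k)

    res <- rmAnovaWilks(M)
    a <- anova(lm(Y ~ 1), test = "Wilks")
    expect_equal(res$statistic, a["(Intercept)", "approx F"], tolerance = 1e-8)
    expect_equal(res$wilks_lambda, a["(Intercept)", "Wilks"], tolerance = 1e-8)
    expect_equal(res$p_value, a["(Intercept)", "Pr(>F)"], tolerance = 1e-8)

    both <- rmAnovaWilks(M, between = z)
    az <- anova(lm(Y ~ z), test = "Wilks")
    expect_equal(both$statistic[2], az["z", "approx F"], tolerance = 1e-8)
    expect_equal(both$wilks_lambda[2], az["z", "Wilks"], tolerance = 1e-8)
    expect_equal(both$p_value[2], az["z", "Pr(>F)"], tolerance = 1e-8)
    expect_true(all(c(both$df1, both$df2) > 0))

    degenerate <- matrix(rep(c(1, 2, 3), each = 6), 6)
    expect_error(rmAnovaWilks(degenerate), "singular|computationally")
})

test_that("Bonferroni correction scales p-values and the alpha threshold", {
    fam <- bonferroni(c(0.016, 0.2), familySize = 6)
    expect_equal(fam$adjusted_alpha, 0.05 / 6)
    expect_equal(round(fam$adjusted_alpha, 3), 0.008)
    expect_equal(fam$p_corrected[1], 0.096)
    expect_false(fam$significant[1])

    expect_equal(bonferroni(0.3, familySize = 1)$p_corrected, 0.3)
    set.seed(1)
    p <- runif(10)
    out <- bonferroni(p, familySize = 12)
    expect_true(all(out$p_corrected >= p))
    expect_true(all(out$p_corrected <= 1))
})
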