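test_that("lesion matrix restricts to voxels covered by enough subjects", {
    a <- maskAt(1:50, id = "a"); b <- maskAt(1:50, id = "b")
    lm2 <- buildLesionMatrix(list(a, b), minOverlap = 2)
    expect_equal(sum(lm2$analysisMask), 50)
    expect_true(all(lm2$lesions == 1))
    expect_equal(dim(lm2$lesions), c(2, 50))

    expect_error(buildLesionMatrix(list(maskAt(1:10), maskAt(11:20)), 2),
                 "empty analysis mask")

    # analysis mask equals the frequency-map thresholded region
    masks <- list(maskAt(c(1, 2, 3)), maskAt(c(2, 3, 4)), maskAt(c(3, 4, 5)))
    lm3 <- buildLesionMatrix(masks, minOverlap = 2)
    fm <- frequencyMap(masks, displayThreshold = 2)
    expect_equal(lm3$analysisMask, array(as.numeric(mapCounts(fm) >= 2),
                                         dim = dim(mapCounts(fm))))
})

test_that("voxel GLM t reduces to the classical two-group / correlation t", {
    set.seed(30)
    n <- 24
    Y <- matrix(rbinom(n * 6, 1, 0.5), n)
    Y <- Y[, apply(Y, 2, sd) > 0, drop = FALSE]
    group <- rep(c(0, 1), each = n / 2)

    got <- glmTMap(Y, voxelwiseDesign(group))
    for (v in seq_len(ncol(Y))) {
        x1 <- Y[group == 1, v]; x0 <- Y[group == 0, v]
        if (sd(x1) == 0 && sd(x0) == 0) next
        tt <- twoSampleT(x1, x0)
        expect_equal(got$t[v], tt$statistic, tolerance = 1e-10)
    }

    pct <- rnorm(n, 30, 10)
    gotC <- glmTMap(Y, voxelwiseDesign(pct))
    for (v in seq_len(ncol(Y))) {
        r <- cor(pct, Y[, v])
        tOracle <- r * sqrt((n - 2) / (1 - r^2))
        expect_equal(gotC$t[v], tOracle, tolerance = 1e-10)
    }

    vol <- rnorm(n, 40, 10)
    gotN <- glmTMap(Y, voxelwiseDesign(pct, nuisance = vol))
    for (v in seq_len(ncol(Y))) {
        pr <- partialR(Y[, v], pct, vol)
        tOracle <- pr$statistic * sqrt(pr$df1 / (1 - pr$statistic^2))
        expect_equal(gotN$t[v], tOracle, tolerance = 1e-8)
    }
})

test_that("exact permutation p equals full enumeration on small cohorts", {
    # independent oracle: enumerate all group assignments by hand at one voxel
    set.seed(44)
    n <- 8
    y <- c(1, 1, 1, 0, 1, 0, 0, 0)
    group <- rep(c(1, 0), each = 4)
    Y <- matrix(y, ncol = 1)
    tStat <- function(g) {
        a <- y[g == 1]; b <- y[g == 0]
        if (sd(a) == 0 && sd(b) == 0) return(0)
        unname(t.test(a, b, var.equal = TRUE)$statistic)
    }
    combos <- combn(n, 4)
    nullT <- apply(combos, 2, function(ix) {
        g <- rep(0, n); g[ix] <- 1
        abs(tStat(g))
    })
    pOracle <- mean(nullT >= abs(tStat(group)) - 1e-12)

    res <- permutationFwe(Y, voxelwiseDesign(group), nPerm = 100, seed = 2)
    expect_true(res@exact)
    expect_equal(res@nPermutations, choose(8, 4))
    expect_equal(as.vector(pFwe(res))[1], pOracle, tolerance = 1e-12)
})

test_that("permutation FWE maps are reproducible and label-exchange invariant", {
    set.seed(55)
    n <- 30
    Y <- matrix(rbinom(n * 40, 1, 0.4), n)
    group <- rbinom(n, 1, 0.5)
    while (sd(group) == 0) group <- rbinom(n, 1, 0.5)
    des <- voxelwiseDesign(group)

    r1 <- permutationFwe(Y, des, nPerm = 60, seed = 9)
    r2 <- permutationFwe(Y, des, nPerm = 60, seed = 9)
    expect_identical(tMap(r1), tMap(r2))
    expect_identical(pFwe(r1), pFwe(r2))

    # relabeling the groups flips t but leaves two-tailed FWE p unchanged
    r3 <- permutationFwe(Y, voxelwiseDesign(1 - group), nPerm = 60, seed = 9)
    expect_equal(tMap(r3), -tMap(r1))
    expect_equal(pFwe(r3), pFwe(r1))

    # enlarging nPerm never changes the observed t-map
    r4 <- permutationFwe(Y, des, nPerm = 120, seed = 9)
    expect_identical(tMap(r4), tMap(r1))

    # p_fwe bounds: [1/(nPerm+1), 1]
    pf <- as.vector(pFwe(r1))
    expect_true(all(pf >= 1 / (r1@nPermutations + 1) - 1e-12 & pf <= 1))
})

test_that("a single random permutation yields p in {0.5, 1}", {
    set.seed(20)
    Y <- matrix(rbinom(200, 1, 0.5), 20)
    pct <- rnorm(20)
    res <- permutationFwe(Y, voxelwiseDesign(pct), nPerm = 1, seed = 4)
    expect_true(all(as.vector(pFwe(res)) %in% c(0.5, 1)))
})

test_that("Freedman-Lane maps differ from naive permutation but share the t-map", {
    set.seed(66)
    n <- 26
    Y <- matrix(rbinom(n * 30, 1, 0.5), n)
    pct <- rnorm(n); vol <- 0.5 * pct + rnorm(n)
    desN <- voxelwiseDesign(pct, nuisance = vol)
    fl <- permutationFwe(Y, desN, nPerm = 50, seed = 3)
    sp <- permutationFwe(Y, desN, nPerm = 50, seed = 3, simplePermutation = TRUE)
    expect_identical(tMap(fl), tMap(sp))
    expect_false(identical(fl@nullMax, sp@nullMax))
})

test_that("the voxel-wise suite runs the planned analyses on a cohort", {
    ch <- fixtureCohort()
    res <- runVoxelwiseSuite(ch$manifest, ch$masks$core, nPerm = 25, seed = 5,
                             minOverlap = 2, flip = "unify_left",
                             analyses = "group")
    expect_setequal(names(res),
                    c("group_unflipped", "group_volcorr_unflipped",
                      "group_flipped", "group_volcorr_flipped"))
    for (r in res) {
        expect_s4_class(r, "VoxelwiseResult")
        expect_equal(r@nSubjects, nrow(ch$manifest))
    }
    res2 <- runVoxelwiseSuite(ch$manifest, ch$masks$core, nPerm = 25, seed = 5,
                              minOverlap = 2, flip = "unify_left",
                              analyses = "group")
    expect_identical(pFwe(res2$group_flipped), pFwe(res$group_flipped))
})

test_that("a strongly planted focal effect is detected, a null is not", {
    # two groups with lesions in different corners of the grid
    set.seed(77)
    n <- 20
    masks <- vector("list", n)
    group <- rep(c(0, 1), each = n / 2)
    for (i in seq_len(n)) {
        base <- if (group[i] == 1) 1:60 else 441:500
        jitterIdx <- sample(setdiff(seq_len(1000), base), 10)
        masks[[i]] <- maskAt(c(base, jitterIdx), id = sprintf("m%02d", i))
    }
    lm0 <- buildLesionMatrix(masks, minOverlap = 2)
    res <- permutationFwe(lm0, voxelwiseDesign(group), nPerm = 200, seed = 8)
    expect_gt(sum(pFwe(res)[analysisMask(res) == 1] <= 0.05, na.rm = TRUE), 0)
})
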