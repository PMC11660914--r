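## Mass-univariate voxel-wise lesion mapping with max-statistic permutation
## FWE correction (randomise-style, reimplemented in-package). The response
## at each voxel is the 0/1 lesion indicator across subjects; the design is
## [intercept, predictor, nuisance...] and the predictor coefficient is
## tested. Without nuisance covariates the predictor labels are permuted;
## with nuisance, the Freedman-Lane scheme permutes reduced-model residuals.

#' Describe a voxel-wise design
#'
#' @param predictor per-subject value: a 0/1 group indicator (e.g. methylated
#'   vs unmethylated) or a continuous covariate (methylation percentage).
#' @param nuisance optional numeric vector or matrix of per-subject nuisance
#'   covariates (e.g. core volume in mL).
#' @param tails `"two"` (default, max |t|) or `"one"` (max t, testing the
#'   positive direction of the predictor coefficient).
#' @return A list of class `voxelwiseDesign`.
#' @export
voxelwiseDesign <- function(predictor, nuisance = NULL, tails = c("two", "one")) {
    tails <- match.arg(tails)
    predictor <- as.numeric(predictor)
    if (anyNA(predictor)) stop("predictor must not contain NA")
    if (sd(predictor) == 0) stop("predictor is constant across subjects")
    if (!is.null(nuisance)) {
        nuisance <- as.matrix(nuisance)
        if (anyNA(nuisance)) stop("nuisance must not contain NA")
        X <- cbind(1, predictor, nuisance)
        if (qr(X)$rank < ncol(X)) stop("rank-deficient design (nuisance collinear)")
    }
    structure(list(predictor = predictor, nuisance = nuisance, tails = tails),
              class = "voxelwiseDesign")
}

#' Build the subjects-by-voxels lesion matrix
#'
#' Restricts the analysis to voxels lesioned in at least `minOverlap`
#' subjects (default 2) and stacks the masks into a binary subjects x voxels
#' matrix over that analysis mask.
#'
#' @param masks list of [LesionMask-class] on one grid (>= 2 masks).
#' @param minOverlap minimum number of overlapping lesions for a voxel to
#'   enter the analysis.
#' @return list with `lesions` (n x V binary matrix), `analysisMask`
#'   (3D 0/1 array), `grid`.
#' @export
buildLesionMatrix <- function(masks, minOverlap = 2) {
    if (length(masks) < 2L) stop("need at least two masks")
    fm <- frequencyMap(masks, displayThreshold = minOverlap)
    amask <- mapCounts(fm) >= minOverlap
    if (!any(amask)) stop("empty analysis mask at minOverlap = ", minOverlap)
    Y <- vapply(masks, function(m) m@values[amask], numeric(sum(amask)))
    list(lesions = t(Y), analysisMask = array(as.numeric(amask), dim = dim(amask)),
         grid = masks[[1]]@grid)
}

## OLS t-statistics for the predictor column over all voxels at once.
## X: n x p design with the tested coefficient in column `cix`; Y: n x V.
.olsT <- function(X, Y, cix = 2L) {
    n <- nrow(X); p <- ncol(X)
    XtXi <- solve(crossprod(X))
    XtY <- crossprod(X, Y)                # p x V
    B <- XtXi %*% XtY
    rss <- colSums(Y^2) - colSums(B * XtY)
    rss[rss < 0] <- 0
    sigma2 <- rss / (n - p)
    se <- sqrt(XtXi[cix, cix] * sigma2)
    tt <- B[cix, ] / se
    tt[se == 0] <- 0
    list(t = tt, df = n - p)
}

#' Voxel-wise GLM t-map
#'
#' Per voxel, ordinary least squares of the lesion indicator on
#' \[intercept, predictor, nuisance...\]; the returned t tests the predictor
#' coefficient with n - p df. With a binary predictor and no nuisance this is
#' exactly the two-sample pooled t on lesion status at each voxel; with a
#' continuous predictor it is the Pearson-correlation t-transform; with
#' nuisance it equals the partial-correlation t.
#'
#' @param lesions n x V binary matrix from [buildLesionMatrix()].
#' @param design a [voxelwiseDesign()].
#' @return list with `t` (length-V vector) and `df`.
#' @export
glmTMap <- function(lesions, design) {
    X <- cbind(1, design$predictor, design$nuisance)
    if (nrow(lesions) != nrow(X)) stop("subjects mismatch between lesions and design")
    if (nrow(X) <= ncol(X) + 1L) stop("too few subjects for the design")
    .olsT(X, lesions)
}

## All distinct relabelings of a binary predictor (choose(n, n1) of them),
## as an n x nPerm matrix of 0/1 columns; used for exact enumeration.
.enumerateBinary <- function(predictor) {
    n <- length(predictor)
    ones <- sum(predictor == max(predictor))
    sets <- combn(n, ones)
    out <- matrix(0, n, ncol(sets))
    out[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = ones))] <- 1
    out
}

.permSpaceSize <- function(predictor) {
    u <- unique(predictor)
    if (length(u) == 2L) choose(length(predictor), sum(predictor == max(u)))
    else factorial(length(predictor))
}

#' Max-statistic permutation FWE correction
#'
#' Computes the observed voxel-wise t-map, then the permutation null
#' distribution of the maximum statistic (|t| for two-tailed, t for
#' one-tailed) over the analysis mask, and the FWE-corrected p-value
#' \eqn{p_{FWE}(v) = (1 + \#\{ \max_{perm} \ge t_{obs}(v) \}) / (n_{perm}+1)}
#' (the observed statistic is included in the null, so p > 0 always).
#' Without nuisance covariates the predictor labels are permuted; with
#' nuisance the Freedman-Lane scheme is used (permute residuals of the
#' reduced model, unless `simplePermutation = TRUE`). When the permutation
#' space has no more than `nPerm` distinct elements it is enumerated
#' exhaustively and the p-values are exact (denominator = the space size,
#' which includes the identity).
#'
#' @param lesions n x V binary matrix (or the list from
#'   [buildLesionMatrix()], in which case maps are returned as arrays).
#' @param design a [voxelwiseDesign()].
#' @param nPerm number of random permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param analysisMask,grid used when `lesions` is a bare matrix and a
#'   [VoxelwiseResult-class] is wanted; otherwise inferred.
#' @param simplePermutation permute the raw predictor even with nuisance.
#' @return A [VoxelwiseResult-class].
#' @export
permutationFwe <- function(lesions, design, nPerm = 1000, seed = 1,
                           analysisMask = NULL, grid = NULL,
                           simplePermutation = FALSE) {
    if (is.list(lesions) && !is.null(lesions$lesions)) {
        analysisMask <- lesions$analysisMask
        grid <- lesions$grid
        lesions <- lesions$lesions
    }
    Y <- lesions
    n <- nrow(Y)
    X <- cbind(1, design$predictor, design$nuisance)
    if (n <= ncol(X) + 1L) stop("too few subjects for the design")
    obs <- .olsT(X, Y)
    twoTailed <- design$tails == "two"
    score <- function(tv) if (twoTailed) abs(tv) else tv

    spaceSize <- .permSpaceSize(design$predictor)
    haveNuisance <- !is.null(design$nuisance) && !simplePermutation
    binaryPred <- length(unique(design$predictor)) == 2L && !haveNuisance
    exact <- is.finite(spaceSize) && spaceSize <= nPerm && (binaryPred || n <= 8L)

    if (haveNuisance) {
        Z <- cbind(1, design$nuisance)
        Hz <- Z %*% solve(crossprod(Z), t(Z))
        Ez <- Y - Hz %*% Y                 # reduced-model residuals
        Fz <- Y - Ez
    }

    permT <- function(ord = NULL, pred = NULL) {
        if (haveNuisance) {
            Ystar <- Fz + Ez[ord, , drop = FALSE]
            .olsT(X, Ystar)$t
        } else {
            Xp <- X
            Xp[, 2] <- if (is.null(pred)) design$predictor[ord] else pred
            .olsT(Xp, Y)$t
        }
    }

    set.seed(seed)
    if (exact) {
        if (binaryPred) {
            lv <- sort(unique(design$predictor))
            preds <- .enumerateBinary(design$predictor)
            nullMax <- apply(preds, 2, function(g)
                max(score(permT(pred = lv[1] + (lv[2] - lv[1]) * g))))
        } else {
            ords <- .allPermutations(n)
            nullMax <- apply(ords, 2, function(o) max(score(permT(ord = o))))
        }
    } else {
        nullMax <- vapply(seq_len(nPerm), function(i)
            max(score(permT(ord = sample.int(n)))), numeric(1))
    }

    sObs <- score(obs$t)
    if (exact) {
        nEff <- length(nullMax)
        pF <- vapply(sObs, function(s) sum(nullMax >= s - 1e-12) / nEff, numeric(1))
    } else {
        nEff <- nPerm
        pF <- vapply(sObs, function(s) (1 + sum(nullMax >= s - 1e-12)) / (nPerm + 1),
                     numeric(1))
    }
    pU <- if (twoTailed) 2 * pt(-abs(obs$t), obs$df)
          else pt(obs$t, obs$df, lower.tail = FALSE)

    if (is.null(grid)) grid <- imageGridCreate(c(1L, 1L, ncol(Y)))
    if (is.null(analysisMask)) analysisMask <- array(1, dim = grid@dims)
    toArr <- function(v) {
        a <- array(NA_real_, dim = grid@dims)
        a[analysisMask == 1] <- v
        a
    }
    new("VoxelwiseResult", grid = grid, tMap = toArr(obs$t),
        pUncorrected = toArr(pU), pFwe = toArr(pF),
        analysisMask = array(as.numeric(analysisMask), dim = grid@dims),
        nPermutations = as.integer(nEff), seed = as.integer(seed),
        tails = design$tails, nullMax = as.numeric(nullMax),
        nSubjects = as.integer(n), exact = exact)
}

.allPermutations <- function(n) {
    if (n > 8L) stop("refusing to enumerate permutations for n > 8")
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- .allPermutations(n - 1L)
    out <- matrix(0L, n, ncol(sub) * n)
    col <- 0L
    for (pos in seq_len(n)) for (j in seq_len(ncol(sub))) {
        col <- col + 1L
        out[, col] <- append(sub[, j], n, after = pos - 1L)
    }
    out
}

#' Run the standard voxel-wise analysis suite
#'
#' Reproduces the full set of voxel-wise lesion-mapping analyses on a cohort:
#' (a) methylated vs unmethylated group contrast, (b) continuous methylation
#' percentage (quantified subjects only), (c) high vs low methylation by
#' median split — each optionally repeated with lesions unified to one
#' hemisphere, and each with or without the core-volume nuisance covariate.
#'
#' @param manifest cohort manifest data.frame (see [generateCohort()]).
#' @param masks named list of core [LesionMask-class] (names = subject ids).
#' @param nPerm permutations per analysis (default 1000).
#' @param seed base seed; each analysis derives its own stream from it.
#' @param minOverlap voxel inclusion threshold (default 2).
#' @param flip `"none"`, `"unify_left"` or `"unify_right"`: also run the
#'   flipped variants.
#' @param volumeCorrection also run each analysis with core volume (mL) as a
#'   nuisance covariate.
#' @param analyses subset of `c("group", "continuous", "median_split")`.
#' @return Named list of [VoxelwiseResult-class] objects; names encode the
#'   analysis, flip state and nuisance state.
#' @export
runVoxelwiseSuite <- function(manifest, masks, nPerm = 1000, seed = 1,
                              minOverlap = 2, flip = "none",
                              volumeCorrection = TRUE,
                              analyses = c("group", "continuous", "median_split")) {
    masks <- masks[manifest$subject_id]
    variants <- list(unflipped = masks)
    if (flip != "none")
        variants$flipped <- lapply(masks, flipLateral, mode = flip)
    results <- list()
    aix <- 0L
    for (vn in names(variants)) {
        lm0 <- buildLesionMatrix(variants[[vn]], minOverlap = minOverlap)
        specs <- list()
        if ("group" %in% analyses) {
            g <- as.numeric(manifest$methylation_status == "methylated")
            specs$group <- list(keep = rep(TRUE, nrow(manifest)), predictor = g)
        }
        if ("continuous" %in% analyses) {
            keep <- !is.na(manifest$methylation_pct) &
                    manifest$methylation_status == "methylated"
            specs$continuous <- list(keep = keep,
                                     predictor = manifest$methylation_pct[keep])
        }
        if ("median_split" %in% analyses) {
            keep <- !is.na(manifest$methylation_pct) &
                    manifest$methylation_status == "methylated"
            ms <- medianSplit(manifest$methylation_pct[keep])
            pred <- numeric(sum(keep)); pred[ms$highIdx] <- 1
            specs$median_split <- list(keep = keep, predictor = pred)
        }
        for (an in names(specs)) {
            sp <- specs[[an]]
            for (nu in (if (volumeCorrection) c(FALSE, TRUE) else FALSE)) {
                aix <- aix + 1L
                nuis <- if (nu) manifest$core_volume[sp$keep] else NULL
                sub <- list(lesions = lm0$lesions[sp$keep, , drop = FALSE],
                            analysisMask = lm0$analysisMask, grid = lm0$grid)
                nm <- paste0(an, if (nu) "_volcorr" else "", "_", vn)
                results[[nm]] <- tryCatch({
                    des <- voxelwiseDesign(sp$predictor, nuisance = nuis)
                    permutationFwe(sub, des, nPerm = nPerm, seed = seed + aix)
                },
                    error = function(e) {
                        message("voxel-wise analysis '", nm, "' skipped: ",
                                conditionMessage(e))
                        NULL
                    })
            }
        }
    }
    results
}
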