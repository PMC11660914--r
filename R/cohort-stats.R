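## Subject-level statistics: MGMT dichotomization (>= 8% rule), median split,
## chi-square / t tests, Pearson and first-order partial correlations, the
## repeated-measures Wilks' lambda test used for network overlap profiles,
## and Bonferroni correction with explicit family sizes. Every test returns a
## tidy one-row (or few-row) data.frame so the pipeline can stack results.

.statRow <- function(test, n, statistic, df1, df2 = NA_real_, p,
                     pCorrected = NA_real_, familySize = NA_integer_) {
    data.frame(test = test, n = as.integer(n), statistic = statistic,
               df1 = df1, df2 = df2, p_value = p, p_corrected = pCorrected,
               family_size = as.integer(familySize), stringsAsFactors = FALSE)
}

#' Dichotomize MGMT promoter methylation percentage
#'
#' A tumour is called methylated when its mean promoter methylation
#' percentage is greater than or equal to the cutoff (default 8%, the
#' inclusive boundary used for pyrosequencing-based calling).
#'
#' @param pct methylation percentage(s) in \[0, 100\]; `NA` allowed.
#' @param cutoff inclusive cutoff in percent (default 8).
#' @return Character vector: `"methylated"` / `"unmethylated"` (`NA` for
#'   missing input).
#' @examples
#' classifyMethylation(c(7.9, 8, 37))
#' @export
classifyMethylation <- function(pct, cutoff = 8) {
    ok <- is.na(pct) | (pct >= 0 & pct <= 100)
    if (!all(ok)) stop("methylation percentage out of [0, 100]")
    ifelse(is.na(pct), NA_character_,
           ifelse(pct >= cutoff, "methylated", "unmethylated"))
}

#' Median split into highly and lowly methylated groups
#'
#' Cutoff is the sample median; values strictly above it form the high group,
#' values at or below it the low group (ties at the median deterministically
#' go low; the assignment is reported in the returned object).
#'
#' @param values numeric vector (length >= 2); `NA` dropped.
#' @return list with `cutoff`, `high`, `low` (values), `highIdx`, `lowIdx`
#'   (indices into the non-missing input), and `nTies` (values equal to the
#'   median, assigned low).
#' @export
medianSplit <- function(values) {
    keep <- which(!is.na(values))
    v <- values[keep]
    if (length(v) < 2L) stop("need at least two non-missing values")
    cutoff <- median(v)
    hi <- v > cutoff
    if (!any(hi) || all(hi))
        warning("degenerate median split: one group is empty")
    list(cutoff = cutoff, high = v[hi], low = v[!hi],
         highIdx = keep[hi], lowIdx = keep[!hi],
         nTies = sum(v == cutoff))
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' The uncorrected Pearson statistic with 1 df; Yates' continuity correction
#' is deliberately not applied.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive margins.
#' @return One-row data.frame (see package overview for the tidy columns).
#' @examples
#' chiSquare2x2(matrix(c(27, 22, 15, 29), 2))  # right/left x methylation status
#' @export
chiSquare2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == 2L)) stop("expected a 2x2 table")
    if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero marginal in table")
    ## the Pearson statistic is returned regardless of expected-count size;
    ## small-count adequacy is the caller's judgement, so the stock warning
    ## is silenced here
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    .statRow("chi_square_2x2", sum(tab), unname(ht$statistic),
             unname(ht$parameter), p = ht$p.value)
}

#' Two-sample t-test (pooled variance by default)
#'
#' Student's t with pooled variance; set `welch = TRUE` for the unequal
#' variance form. Two groups with zero pooled variance and equal means give
#' t = 0, p = 1; zero variance with unequal means is an error.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param twoTailed two-tailed p (default) or upper-tail.
#' @param welch use Welch's unequal-variance form.
#' @return One-row data.frame.
#' @export
twoSampleT <- function(x, y, twoTailed = TRUE, welch = FALSE) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
    if (sd(x) == 0 && sd(y) == 0) {
        if (mean(x) == mean(y))
            return(.statRow("two_sample_t", length(x) + length(y), 0,
                            length(x) + length(y) - 2, p = 1))
        stop("zero pooled variance with unequal means")
    }
    ht <- stats::t.test(x, y, var.equal = !welch,
                        alternative = if (twoTailed) "two.sided" else "greater")
    .statRow(if (welch) "welch_t" else "two_sample_t", length(x) + length(y),
             unname(ht$statistic), unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors (pairwise complete, n >= 3, non-constant).
#' @return One-row data.frame; `statistic` is r, `df1` is n - 2.
#' @export
pearsonR <- function(x, y) {
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("need n >= 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0) stop("constant input")
    ht <- stats::cor.test(x, y, method = "pearson")
    .statRow("pearson_r", length(x), unname(ht$estimate), unname(ht$parameter),
             p = ht$p.value)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single nuisance variable `z` (here typically tumour core volume):
#' \deqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#'       \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' with a two-tailed p from the t-transform on n - 3 df.
#'
#' @param x,y,z numeric vectors (pairwise complete, n >= 4, non-constant).
#' @return One-row data.frame; `statistic` is the partial r, `df1` is n - 3.
#' @export
partialR <- function(x, y, z) {
    keep <- complete.cases(x, y, z)
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    n <- length(x)
    if (n < 4L) stop("need n >= 4 complete triples")
    if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) stop("constant input")
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
        stop("z is collinear with x or y; partial correlation undefined")
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    df <- n - 3
    tval <- r * sqrt(df / (1 - r^2))
    .statRow("partial_r", n, r, df, p = 2 * pt(-abs(tval), df))
}

## Orthonormal within-subject difference contrasts (k x (k-1)); columns are
## orthogonal to the intercept and to each other with unit norm.
.diffContrasts <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Repeated-measures test via Wilks' lambda
#'
#' Multivariate approach to a one-way within-subject design: the k condition
#' measures per subject (here, a lesion's overlap ratios across k functional
#' networks) are reduced to k - 1 orthonormal difference contrasts and the
#' hypothesis of equal condition means is tested with Wilks' lambda
#' \eqn{\Lambda = \det(E)/\det(E + H)}, converted to an exact F with
#' (k - 1, n - k + 1) df. When a between-subject covariate is supplied
#' (e.g. methylation status coded 0/1), the condition-by-covariate
#' interaction — whether the profile across conditions depends on the
#' covariate — is additionally tested by Wilks' lambda on the contrast scores
#' regressed on the covariate, with (k - 1, n - k) df.
#'
#' @param measures n x k numeric matrix (subjects x conditions), no `NA`.
#' @param between optional numeric per-subject covariate.
#' @return data.frame with one row for the condition effect and, when
#'   `between` is given, one row for the interaction; `statistic` is the F
#'   value and the Wilks' lambda is in column `wilks_lambda`.
#' @export
rmAnovaWilks <- function(measures, between = NULL) {
    M <- as.matrix(measures)
    if (anyNA(M)) {
        keep <- complete.cases(M) & (if (is.null(between)) TRUE else !is.na(between))
        message(sum(!keep), " subject(s) with missing measures dropped listwise")
        M <- M[keep, , drop = FALSE]
        if (!is.null(between)) between <- between[keep]
    }
    n <- nrow(M); k <- ncol(M)
    if (k < 2L) stop("need at least two conditions")
    if (n <= k - 1L) stop("need n > k - 1 subjects")
    Y <- M %*% .diffContrasts(k)
    q <- k - 1L

    wilksF <- function(E, H, dfErr) {
        dE <- det(E)
        if (!is.finite(dE) || dE <= 0)
            stop("singular contrast-score covariance")
        lam <- dE / det(E + H)
        if (!is.finite(lam) || lam <= 0) stop("singular contrast-score covariance")
        ## hypothesis df = 1 -> the Wilks F is exact
        Fval <- ((dfErr - q + 1) / q) * (1 - lam) / lam
        c(lambda = lam, F = Fval, df1 = q, df2 = dfErr - q + 1)
    }

    ybar <- colMeans(Y)
    E <- crossprod(sweep(Y, 2, ybar))
    if (!is.null(between)) {
        z <- as.numeric(between)
        if (sd(z) == 0) stop("between-subject covariate is constant")
        zc <- z - mean(z)
        B <- crossprod(zc, Y) / sum(zc^2)          # 1 x q slope
        fitted <- outer(zc, drop(B))
        Ez <- E - crossprod(fitted)                 # residual SSCP of Y ~ 1 + z
        Hz <- crossprod(fitted)
        cond <- wilksF(Ez, n * tcrossprod(ybar)[seq_len(q), seq_len(q), drop = FALSE],
                       n - 2L)
        intr <- wilksF(Ez, Hz, n - 2L)
        out <- rbind(
            .statRow("rm_condition", n, cond["F"], cond["df1"], cond["df2"],
                     p = pf(cond["F"], cond["df1"], cond["df2"], lower.tail = FALSE)),
            .statRow("rm_condition_x_covariate", n, intr["F"], intr["df1"],
                     intr["df2"],
                     p = pf(intr["F"], intr["df1"], intr["df2"], lower.tail = FALSE)))
        out$wilks_lambda <- c(cond["lambda"], intr["lambda"])
        rownames(out) <- NULL
        return(out)
    }
    H <- n * tcrossprod(ybar)
    res <- wilksF(E, H, n - 1L)
    out <- .statRow("rm_condition", n, res["F"], res["df1"], res["df2"],
                    p = pf(res["F"], res["df1"], res["df2"], lower.tail = FALSE))
    out$wilks_lambda <- res["lambda"]
    rownames(out) <- NULL
    out
}

#' Bonferroni correction with an explicit family size
#'
#' Corrected p = min(1, p * familySize); the adjusted alpha 0.05 / familySize
#' is returned alongside (e.g. six pairwise comparisons give alpha 0.0083,
#' reported as significance at p < 0.008).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param familySize number of tests in the family (default `length(p)`,
#'   must be >= `length(p)`).
#' @param alpha nominal family-wise level (default 0.05).
#' @return list with `p_corrected`, `adjusted_alpha`, `family_size`,
#'   `significant` (logical at the adjusted alpha, on the raw p).
#' @export
bonferroni <- function(p, familySize = length(p), alpha = 0.05) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    if (familySize < length(p)) stop("familySize must be >= length(p)")
    pc <- stats::p.adjust(p, method = "bonferroni", n = familySize)
    list(p_corrected = pc, adjusted_alpha = alpha / familySize,
         family_size = as.integer(familySize), significant = p < alpha / familySize)
}
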