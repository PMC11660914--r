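## Config-driven orchestration: load a cohort from disk (or take a generated
## one), validate it, and run the full analysis sequence — overlap profiling,
## categorical group tests, network repeated-measures tests, compartment
## correlations, frequency maps, and the voxel-wise permutation suite —
## writing tidy TSV results, NIfTI maps and a run log. A single global seed
## fans out to per-stage seeds through a stable string hash so any stage can
## be rerun in isolation.

.stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Load a cohort directory written by [writeCohort()]
#'
#' @param dir directory containing `manifest.tsv`, `masks/` and `atlases/`.
#' @return A list shaped like a `gbmCohort` (manifest, masks, template).
#' @export
loadCohortDir <- function(dir) {
    man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                             stringsAsFactors = FALSE)
    atl <- list()
    grid <- NULL
    for (nm in c("lobes", "tissue", "gmn", "wmn")) {
        atl[[nm]] <- readAtlas(file.path(dir, "atlases", paste0(nm, ".nii.gz")),
                               file.path(dir, "atlases", paste0(nm, ".tsv")),
                               gridRef = grid)
        if (is.null(grid)) grid <- atl[[nm]]@grid
    }
    readSet <- function(col, comp) {
        ms <- lapply(seq_len(nrow(man)), function(s)
            readMask(file.path(dir, man[[col]][s]), gridRef = grid,
                     compartment = comp, subjectId = man$subject_id[s]))
        names(ms) <- man$subject_id
        ms
    }
    core <- readSet("core_mask", "core")
    oed <- readSet("oedema_mask", "oedema")
    glob <- mapply(globalMask, core, oed, SIMPLIFY = FALSE)
    structure(list(manifest = man,
                   masks = list(core = core, oedema = oed, global = glob),
                   template = c(atl, list(grid = grid))),
              class = "gbmCohort")
}

#' Validate cohort inputs
#'
#' Checks the manifest schema, the consistency of the stored methylation
#' status with the dichotomization rule, volume bookkeeping
#' (global >= max(core, oedema)), grid agreement across atlases and masks,
#' and that every atlas label present in a volume appears in its table.
#' Violations are returned as data, not raised.
#'
#' @param cohort a `gbmCohort` (from [generateCohort()] or [loadCohortDir()]).
#' @param cutoff methylation dichotomization cutoff (%).
#' @return data.frame with columns `check`, `subject`, `message`; zero rows
#'   when the cohort is clean.
#' @export
validateInputs <- function(cohort, cutoff = 8) {
    v <- list()
    add <- function(check, subject, message)
        v[[length(v) + 1L]] <<- data.frame(check = check, subject = subject,
                                           message = message)
    man <- cohort$manifest
    need <- c("subject_id", "age", "sex", "methylation_pct",
              "methylation_status", "core_volume", "oedema_volume",
              "global_volume")
    miss <- setdiff(need, names(man))
    if (length(miss))
        add("manifest_schema", "", paste("missing columns:",
                                         paste(miss, collapse = ", ")))
    if (!length(miss)) {
        has <- !is.na(man$methylation_pct)
        derived <- classifyMethylation(man$methylation_pct[has], cutoff)
        bad <- which(derived != man$methylation_status[has])
        for (b in bad)
            add("status_consistency", man$subject_id[has][b],
                sprintf("pct %.1f inconsistent with status '%s' at cutoff %g",
                        man$methylation_pct[has][b],
                        man$methylation_status[has][b], cutoff))
        badVol <- which(man$global_volume + 1e-6 <
                        pmax(man$core_volume, man$oedema_volume))
        for (b in badVol)
            add("volume_bookkeeping", man$subject_id[b],
                "global volume smaller than core or oedema")
    }
    grid <- cohort$template$grid
    for (nm in c("lobes", "tissue", "gmn", "wmn")) {
        a <- cohort$template[[nm]]
        if (!checkSameGrid(a@grid, grid))
            add("grid", nm, "atlas grid differs from the template grid")
        present <- setdiff(unique(as.integer(a@labels)), 0L)
        orphan <- setdiff(present, a@table$label_id)
        if (length(orphan))
            add("atlas_table", nm, paste("labels missing from table:",
                                         paste(orphan, collapse = ", ")))
    }
    for (m in cohort$masks$core)
        if (!checkSameGrid(m@grid, grid))
            add("grid", subjectId(m), "mask grid differs from the template grid")
    if (length(v)) do.call(rbind, v)
    else data.frame(check = character(), subject = character(),
                    message = character())
}

#' Run the full lesion-topology / methylation analysis
#'
#' Executes, in order: overlap profiling (tissue fractions, network ratios,
#' lobar involvement), categorical group tests (hemisphere chi-square, volume
#' t-tests overall and across the four status-by-side categories with
#' Bonferroni correction, per-lobe involvement chi-squares), the grey- and
#' white-matter network repeated-measures Wilks' lambda tests with the
#' methylation-status covariate, compartment correlations (Pearson and
#' volume-corrected partial) for the quantified methylated subset, group
#' frequency maps, and the voxel-wise permutation suite (unflipped and
#' flipped). Writes tidy TSV results, NIfTI maps and a run log under
#' `outDir`.
#'
#' @param cohort a `gbmCohort`.
#' @param outDir output directory.
#' @param nPerm permutations for the voxel-wise suite.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param alpha significance level (default 0.05).
#' @param lobarMinVoxels lobar involvement threshold (default 250; scale to
#'   the grid when using reduced synthetic templates).
#' @param freqThreshold frequency-map display threshold (default 2).
#' @param minOverlap voxel-wise analysis-mask threshold (default 2).
#' @param flip flip mode for the flipped voxel-wise repeat
#'   (`"unify_left"`, `"unify_right"`, `"none"`).
#' @param cutoff methylation dichotomization cutoff (default 8).
#' @param voxelwise run the (costly) voxel-wise stage (default TRUE).
#' @return Invisibly, a list with `results` (tidy data.frame), `overlap`
#'   tables, `frequencyMaps`, `voxelwise` results and `log`.
#' @export
runFullAnalysis <- function(cohort, outDir, nPerm = 1000, seed = 1,
                            alpha = 0.05, lobarMinVoxels = 250,
                            freqThreshold = 2, minOverlap = 2,
                            flip = "unify_left", cutoff = 8,
                            voxelwise = TRUE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    viol <- validateInputs(cohort, cutoff = cutoff)
    if (nrow(viol)) {
        utils::write.table(viol, file.path(outDir, "violations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stop("input validation failed (", nrow(viol),
             " violation(s)); see violations.tsv")
    }
    man <- cohort$manifest
    core <- cohort$masks$core[man$subject_id]
    tpl <- cohort$template
    results <- list()
    logRows <- list()
    note <- function(stage, msg)
        logRows[[length(logRows) + 1L]] <<- data.frame(stage = stage, note = msg)

    ## ---- stage 1: overlap profiling ----
    tissueTab <- overlapTable(core, tpl$tissue, "fraction")
    gmnTab <- overlapTable(core, tpl$gmn, "ratio")
    wmnTab <- overlapTable(core, tpl$wmn, "ratio")
    lobeSets <- lapply(core, lobarInvolvement, lobes = tpl$lobes,
                       minVoxels = lobarMinVoxels)
    lobeNames <- tpl$lobes@table$region_name
    lobeTab <- data.frame(subject_id = man$subject_id,
                          sapply(lobeNames, function(L)
                              vapply(lobeSets, function(s) L %in% s, logical(1))),
                          row.names = NULL)
    for (nm in c("tissueTab", "gmnTab", "wmnTab", "lobeTab"))
        utils::write.table(get(nm), file.path(outDir, paste0(sub("Tab", "", nm),
                                                             "_overlap.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    note("overlap", sprintf("lobar threshold %d voxels", lobarMinVoxels))

    addResult <- function(analysis, row) {
        row$analysis <- analysis
        results[[length(results) + 1L]] <<- row
    }

    ## ---- stage 2: categorical group tests ----
    isMeth <- man$methylation_status == "methylated"
    tabSide <- table(factor(isMeth, c(TRUE, FALSE)),
                     factor(man$hemisphere, c("right", "left")))
    addResult("hemisphere_x_status", chiSquare2x2(as.matrix(tabSide)))
    for (volCol in c("core_volume", "oedema_volume", "global_volume"))
        addResult(paste0(volCol, "_by_status"),
                  twoSampleT(man[[volCol]][isMeth], man[[volCol]][!isMeth]))
    ## four status x side categories: 6 pairwise global-volume comparisons
    cat4 <- interaction(ifelse(isMeth, "meth", "unmeth"), man$hemisphere)
    lv <- levels(droplevels(cat4))
    pairRows <- list()
    if (length(lv) == 4L) {
        prs <- combn(lv, 2)
        for (pix in seq_len(ncol(prs))) {
            a <- man$global_volume[cat4 == prs[1, pix]]
            b <- man$global_volume[cat4 == prs[2, pix]]
            if (length(a) >= 2 && length(b) >= 2) {
                row <- twoSampleT(a, b)
                row$analysis <- paste("global_volume", prs[1, pix], "vs",
                                      prs[2, pix])
                pairRows[[length(pairRows) + 1L]] <- row
            }
        }
        fam <- bonferroni(vapply(pairRows, function(r) r$p_value, numeric(1)),
                          familySize = 6, alpha = alpha)
        for (pix in seq_along(pairRows)) {
            pairRows[[pix]]$p_corrected <- fam$p_corrected[pix]
            pairRows[[pix]]$family_size <- fam$family_size
            results[[length(results) + 1L]] <- pairRows[[pix]]
        }
        note("volume_4cat", sprintf("Bonferroni family 6, adjusted alpha %.3f",
                                    fam$adjusted_alpha))
    }
    ## per-lobe involvement x status chi-squares (Bonferroni over lobes)
    lobeP <- c()
    for (L in lobeNames) {
        inv <- lobeTab[[L]]
        tb <- table(factor(isMeth, c(TRUE, FALSE)), factor(inv, c(TRUE, FALSE)))
        if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) {
            row <- chiSquare2x2(as.matrix(tb))
            row$analysis <- paste0("lobe_", L, "_x_status")
            results[[length(results) + 1L]] <- row
            lobeP <- c(lobeP, row$p_value)
        }
    }

    ## ---- stage 3: network repeated-measures tests ----
    for (fam in c("gmn", "wmn")) {
        M <- as.matrix(get(paste0(fam, "Tab"))[, -1, drop = FALSE])
        keep <- complete.cases(M)
        if (sum(!keep)) note(fam, sprintf("%d subject(s) dropped listwise", sum(!keep)))
        if (sum(keep) <= ncol(M) - 1L) {
            note(fam, sprintf("repeated-measures test skipped: n = %d <= k - 1 = %d",
                              sum(keep), ncol(M) - 1L))
            next
        }
        rows <- tryCatch(rmAnovaWilks(M[keep, , drop = FALSE],
                                      between = as.numeric(isMeth)[keep]),
                         error = function(e) {
                             note(fam, paste("repeated-measures test skipped:",
                                             conditionMessage(e)))
                             NULL
                         })
        for (rix in seq_len(NROW(rows)))
            addResult(paste0(fam, "_rm_anova"), rows[rix, , drop = FALSE])
    }

    ## ---- stage 4: compartment correlations (quantified methylated subset) ----
    qIdx <- which(isMeth & !is.na(man$methylation_pct))
    pctQ <- man$methylation_pct[qIdx]
    tryAdd <- function(analysis, expr)
        tryCatch(addResult(analysis, expr),
                 error = function(e) note(analysis, paste("skipped:",
                                                          conditionMessage(e))))
    for (volCol in c("core_volume", "oedema_volume", "global_volume"))
        tryAdd(paste0("pct_vs_", volCol), pearsonR(pctQ, man[[volCol]][qIdx]))
    for (cls in c("cortex", "white_matter", "deep_grey")) {
        fr <- tissueTab[[cls]][qIdx]
        tryAdd(paste0("pct_vs_", cls, "_fraction"), pearsonR(pctQ, fr))
        tryAdd(paste0("pct_vs_", cls, "_fraction_volcorr"),
               partialR(pctQ, fr, man$core_volume[qIdx]))
    }

    ## ---- stage 5: frequency maps ----
    fmaps <- list(
        methylated = frequencyMap(core[isMeth], freqThreshold, "methylated"),
        unmethylated = frequencyMap(core[!isMeth], freqThreshold, "unmethylated"))
    for (gnm in names(fmaps)) {
        writeNiftiVolume(fmaps[[gnm]],
                         file.path(outDir, paste0("freq_", gnm, "_raw.nii.gz")))
        writeNiftiVolume(displayCounts(fmaps[[gnm]]),
                         file.path(outDir, paste0("freq_", gnm, "_thr.nii.gz")),
                         grid = fmaps[[gnm]]@grid)
    }

    ## ---- stage 6: voxel-wise suite ----
    vw <- NULL
    if (voxelwise) {
        vwSeed <- .stageSeed(seed, "voxelwise")
        vw <- runVoxelwiseSuite(man, core, nPerm = nPerm, seed = vwSeed,
                                minOverlap = minOverlap, flip = flip)
        vwLog <- do.call(rbind, lapply(names(vw), function(nm) {
            r <- vw[[nm]]
            data.frame(analysis = nm, n = r@nSubjects,
                       n_perm = r@nPermutations, seed = r@seed,
                       n_voxels = sum(r@analysisMask),
                       n_significant = sum(r@pFwe[r@analysisMask == 1] <= alpha))
        }))
        utils::write.table(vwLog, file.path(outDir, "voxelwise_log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (nm in names(vw)) {
            writeNiftiVolume(ifelse(is.na(vw[[nm]]@tMap), 0, vw[[nm]]@tMap),
                             file.path(outDir, paste0("vw_", nm, "_t.nii.gz")),
                             grid = vw[[nm]]@grid)
            writeNiftiVolume(ifelse(is.na(vw[[nm]]@pFwe), 1, vw[[nm]]@pFwe),
                             file.path(outDir, paste0("vw_", nm, "_pfwe.nii.gz")),
                             grid = vw[[nm]]@grid)
        }
    }

    res <- do.call(rbind, lapply(results, function(r) {
        r$wilks_lambda <- if ("wilks_lambda" %in% names(r)) r$wilks_lambda else NA_real_
        r[, c("analysis", "test", "n", "statistic", "df1", "df2", "p_value",
              "p_corrected", "family_size", "wilks_lambda")]
    }))
    utils::write.table(res, file.path(outDir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("run", sprintf("seed %d, nPerm %d, alpha %g, cutoff %g", seed, nPerm,
                        alpha, cutoff))
    logDf <- do.call(rbind, logRows)
    utils::write.table(logDf, file.path(outDir, "run_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(list(results = res,
                   overlap = list(tissue = tissueTab, gmn = gmnTab,
                                  wmn = wmnTab, lobes = lobeTab),
                   frequencyMaps = fmaps, voxelwise = vw, log = logDf))
}
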