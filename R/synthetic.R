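## Synthetic cohort generator: a mirror-symmetric template brain with lobar /
## tissue / functional-network parcellations, stochastic region-grown lesions
## (core + oedema shell), and molecular data with the statistical structure
## the analysis assumes — in particular a planted positive correlation
## between methylation percentage and the lesion's cortical overlap fraction.
## Everything is seed-reproducible; no external atlas or image is needed.

#' Parameters of a synthetic cohort
#'
#' The defaults encode the study conditions of the cohort the package
#' emulates: 93 subjects, 42 methylated, 41 of those with a quantified
#' methylation percentage (mean 33.9, SD 18.3, floor 8 for the methylated
#' subset), core volume 43.2 +/- 29.3 mL, oedema 54.8 +/- 43.4 mL, and a
#' planted correlation of +0.36 between methylation percentage and cortical
#' overlap fraction (the deep-grey anticorrelation, target about -0.35,
#' arises through the compositional cortex/deep trade-off and is verified
#' rather than independently planted).
#'
#' @param nSubjects,nMethylated,nQuantified cohort sizes.
#' @param methylationMean,methylationSd,methylationFloor moments (%) of the
#'   quantified methylated subset; values are clipped at the floor.
#' @param coreVolumeMean,coreVolumeSd,oedemaVolumeMean,oedemaVolumeSd lesion
#'   volume moments in mL (truncated at > 1 mL).
#' @param plantedRCortex,plantedRDeep target correlations.
#' @param gridDims template grid (default 64^3).
#' @param voxelSizeMm isotropic voxel size (default 2 mm).
#' @param seed integer seed.
#' @param preset `"default"`, `"fixtures"` (5-subject micro-cohort on a 24^3
#'   grid for unit tests) or `"calibration"` (full cohort sizes on a reduced
#'   32^3 / 4 mm grid for permutation calibration runs).
#' @return A list of class `cohortSpec`.
#' @export
syntheticCohortSpec <- function(nSubjects = 93, nMethylated = 42, nQuantified = 41,
                                methylationMean = 33.9, methylationSd = 18.3,
                                methylationFloor = 8,
                                coreVolumeMean = 43.2, coreVolumeSd = 29.3,
                                oedemaVolumeMean = 54.8, oedemaVolumeSd = 43.4,
                                plantedRCortex = 0.36, plantedRDeep = -0.35,
                                gridDims = c(64L, 64L, 64L), voxelSizeMm = 2,
                                seed = 1, preset = c("default", "fixtures",
                                                     "calibration")) {
    preset <- match.arg(preset)
    spec <- list(nSubjects = nSubjects, nMethylated = nMethylated,
                 nQuantified = nQuantified, methylationMean = methylationMean,
                 methylationSd = methylationSd, methylationFloor = methylationFloor,
                 coreVolumeMean = coreVolumeMean, coreVolumeSd = coreVolumeSd,
                 oedemaVolumeMean = oedemaVolumeMean, oedemaVolumeSd = oedemaVolumeSd,
                 plantedRCortex = plantedRCortex, plantedRDeep = plantedRDeep,
                 gridDims = as.integer(gridDims), voxelSizeMm = voxelSizeMm,
                 seed = as.integer(seed))
    if (preset == "fixtures") {
        spec$nSubjects <- 5L; spec$nMethylated <- 3L; spec$nQuantified <- 3L
        spec$coreVolumeMean <- 8; spec$coreVolumeSd <- 3
        spec$oedemaVolumeMean <- 10; spec$oedemaVolumeSd <- 4
        spec$gridDims <- c(24L, 24L, 24L); spec$voxelSizeMm <- 4
    } else if (preset == "calibration") {
        spec$gridDims <- c(32L, 32L, 32L); spec$voxelSizeMm <- 4
    }
    stopifnot(spec$nMethylated <= spec$nSubjects,
              spec$nQuantified <= spec$nMethylated,
              abs(spec$plantedRCortex) < 1, spec$methylationSd > 0)
    structure(spec, class = "cohortSpec")
}

#' Generate the synthetic template and its parcellations
#'
#' Builds a mirror-symmetric ellipsoidal "brain" on a centred grid (world x
#' runs along the first voxel axis, so the mid-sagittal plane is at world
#' x = 0) and parcels it into: an outer cortical ribbon, interior white
#' matter, two bilateral pairs of deep grey nuclei; five angular lobar
#' sectors; a grey-matter network atlas of five cortical parcels plus the two
#' deep-grey pairs as additional parcels (7 total); and a white-matter
#' network atlas of four parcels. All parcellations share the grid and are
#' symmetric under left-right reflection.
#'
#' @param dims integer(3) grid dimensions (each >= 16).
#' @param voxelSizeMm isotropic voxel size.
#' @return list of class `gbmTemplate` with elements `grid`
#'   ([ImageGrid-class]), `brain` (logical array), and [LabelAtlas-class]
#'   objects `lobes`, `tissue`, `gmn`, `wmn`.
#' @export
generateTemplate <- function(dims = c(64L, 64L, 64L), voxelSizeMm = 2) {
    dims <- as.integer(dims)
    if (any(dims < 16L)) stop("dims too small to contain all compartments (need >= 16)")
    grid <- imageGridCreate(dims, voxelSizeMm = voxelSizeMm)
    cx <- (dims + 1) / 2
    i <- (seq_len(dims[1]) - cx[1]); j <- (seq_len(dims[2]) - cx[2])
    k <- (seq_len(dims[3]) - cx[3])
    rad <- c(0.40, 0.45, 0.38) * dims
    U <- array(rep(i / rad[1], times = dims[2] * dims[3]), dim = dims)
    V <- array(rep(rep(j / rad[2], each = dims[1]), times = dims[3]), dim = dims)
    W <- array(rep(k / rad[3], each = dims[1] * dims[2]), dim = dims)
    brain <- U^2 + V^2 + W^2 <= 1
    thick <- max(1L, round(dims[1] / 32))
    radIn <- rad - thick
    inner <- (U * rad[1] / radIn[1])^2 + (V * rad[2] / radIn[2])^2 +
             (W * rad[3] / radIn[3])^2 <= 1

    ## two bilateral pairs of deep grey blobs (absolute x -> mirror symmetric)
    blob <- function(xc, yc, zc, r) {
        ((abs(U) - xc) / r[1])^2 + ((V - yc) / r[2])^2 + ((W - zc) / r[3])^2 <= 1
    }
    rBlob <- c(0.20, 0.20, 0.20)
    deepA <- blob(0.30, 0.18, 0, rBlob) & inner
    deepB <- blob(0.30, -0.18, 0, rBlob) & inner
    deep <- deepA | deepB
    cortex <- brain & !inner
    wm <- inner & !deep

    tissueLab <- array(0L, dim = dims)
    tissueLab[cortex] <- 1L
    tissueLab[wm] <- 2L
    tissueLab[deepA] <- 3L
    tissueLab[deepB] <- 4L
    tissueTab <- data.frame(
        label_id = 1:4,
        region_name = c("cortex", "white_matter", "deep_grey_anterior",
                        "deep_grey_posterior"),
        tissue_class = c("cortex", "white_matter", "deep_grey", "deep_grey"))

    ## five angular sectors in the (y, z) plane -> bilateral lobes
    theta <- atan2(W, V)                 # (-pi, pi], x-independent
    sector <- function(t, nSec, offset = 0) {
        s <- floor(((t + pi + offset) %% (2 * pi)) / (2 * pi / nSec)) + 1L
        pmin(s, nSec)
    }
    lobeLab <- array(0L, dim = dims)
    lobeLab[brain] <- sector(theta[brain], 5L)
    lobeNames <- c("frontal", "insular", "temporal", "parietal", "occipital")
    lobeTab <- data.frame(label_id = 1:5, region_name = lobeNames,
                          tissue_class = "lobe")

    ## grey-matter networks: 5 cortical sectors (offset) + 2 deep parcels
    gmnLab <- array(0L, dim = dims)
    gmnLab[cortex] <- sector(theta[cortex], 5L, offset = pi / 5)
    gmnLab[deepA] <- 6L
    gmnLab[deepB] <- 7L
    gmnTab <- data.frame(label_id = 1:7,
                         region_name = c(paste0("gmn_", 1:5),
                                         "gmn_deep_anterior", "gmn_deep_posterior"),
                         tissue_class = "gm_network")

    ## white-matter networks: 4 quadrant sectors
    wmnLab <- array(0L, dim = dims)
    wmnLab[wm] <- sector(theta[wm], 4L, offset = pi / 4)
    wmnTab <- data.frame(label_id = 1:4, region_name = paste0("wmn_", 1:4),
                         tissue_class = "wm_network")

    ## cached per-class seed-candidate voxels, split by hemisphere (first
    ## voxel axis carries world x; the midplane sits between the two halves)
    iIdx <- array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims)
    mid <- (dims[1] + 1) / 2
    classVoxels <- lapply(list(cortex = cortex, white_matter = wm,
                               deep_grey = deep), function(m) {
        w <- which(m)
        list(left = w[iIdx[w] < mid], right = w[iIdx[w] > mid], all = w)
    })
    structure(list(grid = grid, brain = brain,
                   lobes = labelAtlas(lobeLab, lobeTab, grid),
                   tissue = labelAtlas(tissueLab, tissueTab, grid),
                   gmn = labelAtlas(gmnLab, gmnTab, grid),
                   wmn = labelAtlas(wmnLab, wmnTab, grid),
                   classVoxels = classVoxels),
              class = "gbmTemplate")
}

## Fast internal mask constructor: mutates a prototype's slots without
## re-running validity (values are built 0/1 by construction here).
.fastMask <- function(proto, values, compartment, subjectId) {
    slot(proto, "values", check = FALSE) <- values
    slot(proto, "compartment", check = FALSE) <- compartment
    slot(proto, "subjectId", check = FALSE) <- subjectId
    proto
}

.maskProto <- function(grid) {
    new("LesionMask", grid = grid,
        values = array(0, dim = grid@dims), compartment = "core",
        subjectId = "")
}

## Sample one seed voxel for lesion growth: pick a tissue class from the bias
## mixture, then a uniform voxel of that class within the requested
## hemisphere (falling back to the whole class when the hemisphere is empty).
.sampleSeedVoxel <- function(template, centreBias, hemisphere) {
    cls <- sample(names(centreBias), 1L, prob = centreBias)
    cv <- template$classVoxels[[cls]]
    cand <- cv[[hemisphere]]
    if (!length(cand)) cand <- cv$all
    cand[sample.int(length(cand), 1L)]
}

#' Grow one synthetic lesion (core + oedema shell)
#'
#' Stochastic 6-connected region growing from a seed voxel sampled according
#' to a tissue-class mixture, until the core reaches the target volume; the
#' oedema is then grown outward from the core surface as a disjoint shell.
#' Both are confined to the brain mask. If growth gets trapped before
#' reaching 90% of the target (possible near the brain boundary), a new seed
#' voxel is drawn, with bounded retries.
#'
#' @param template a `gbmTemplate` from [generateTemplate()].
#' @param centreBias named weights over
#'   `c(cortex, white_matter, deep_grey)` for the seed-voxel tissue class.
#' @param targetVolumeMl,oedemaVolumeMl target volumes in mL.
#' @param subjectId subject identifier stamped on the masks.
#' @param hemisphere `"left"` or `"right"` seed hemisphere.
#' @return list with [LesionMask-class] elements `core` and `oedema`.
#' @export
generateLesion <- function(template,
                           centreBias = c(cortex = 0.6, white_matter = 0.25,
                                          deep_grey = 0.15),
                           targetVolumeMl = 43.2, oedemaVolumeMl = 54.8,
                           subjectId = "synthetic", hemisphere = "left") {
    vv <- voxelVolume(template$grid)
    dims <- gridDims(template$grid)
    nCore <- max(8L, round(targetVolumeMl * 1000 / vv))
    nOed <- max(8L, round(oedemaVolumeMl * 1000 / vv))
    allowed <- as.logical(template$brain)
    for (try in 1:20) {
        seedVox <- .sampleSeedVoxel(template, centreBias, hemisphere)
        coreIdx <- .growRegion(allowed, dims, as.integer(seedVox), as.integer(nCore))
        if (length(coreIdx) >= 0.9 * nCore) break
        if (try == 20) stop("lesion growth trapped after 20 seed retries")
    }
    allowedOed <- allowed; allowedOed[coreIdx] <- FALSE
    oedIdx <- .growRegion(allowedOed, dims, as.integer(coreIdx), as.integer(nOed),
                          includeSeeds = FALSE)
    coreArr <- numeric(prod(dims)); coreArr[coreIdx] <- 1; dim(coreArr) <- dims
    oedArr <- numeric(prod(dims)); oedArr[oedIdx] <- 1; dim(oedArr) <- dims
    proto <- template$maskProto
    if (is.null(proto)) proto <- .maskProto(template$grid)
    list(core = .fastMask(proto, coreArr, "core", subjectId),
         oedema = .fastMask(proto, oedArr, "oedema", subjectId))
}

.truncNorm <- function(n, mean, sd, lower = 1) {
    out <- rnorm(n, mean, sd)
    bad <- which(out <= lower)
    while (length(bad)) {
        out[bad] <- rnorm(length(bad), mean, sd)
        bad <- which(out <= lower)
    }
    out
}

#' Generate a full synthetic cohort with a planted cortical correlation
#'
#' Draws demographics and lesion volumes from the spec's (truncated normal)
#' moments, grows every subject's core and oedema masks with per-subject
#' centre bias, and then generates the methylation percentage of the
#' quantified methylated subset as a linear function of each subject's
#' realized cortical overlap fraction plus noise calibrated by
#' \eqn{sd_{noise} = sd_{signal}\sqrt{1/r^2 - 1}} so the pre-clipping
#' correlation equals the planted value; values are clipped to
#' \[floor, 100\] and the post-clipping (attenuated) correlation is measured
#' and reported, not silently corrected. Unmethylated subjects receive a
#' percentage below the dichotomization cutoff; one methylated subject is
#' left without a quantified percentage when `nQuantified < nMethylated`.
#' The deep-grey anticorrelation is not independently planted: it emerges
#' from the compositional trade-off between cortical and deep overlap.
#'
#' @param spec a [syntheticCohortSpec()].
#' @param template optionally reuse an existing `gbmTemplate`.
#' @return list of class `gbmCohort`: `manifest` (data.frame), `masks`
#'   (lists `core`, `oedema`, `global` of [LesionMask-class], named by
#'   subject), `template`, `spec`, and `plantInfo` (pre- and post-clipping
#'   achieved correlations).
#' @export
generateCohort <- function(spec = syntheticCohortSpec(), template = NULL) {
    set.seed(spec$seed)
    if (is.null(template))
        template <- generateTemplate(spec$gridDims, spec$voxelSizeMm)
    n <- spec$nSubjects
    ids <- sprintf("sub%03d", seq_len(n))
    status <- sample(c(rep("methylated", spec$nMethylated),
                       rep("unmethylated", n - spec$nMethylated)))
    age <- round(rnorm(n, 62.3, 11.3), 1)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(66, 27) / 93)
    hemisphere <- sample(c("left", "right"), n, replace = TRUE)
    coreVol <- .truncNorm(n, spec$coreVolumeMean, spec$coreVolumeSd)
    oedVol <- .truncNorm(n, spec$oedemaVolumeMean, spec$oedemaVolumeSd)

    coreMasks <- oedMasks <- globMasks <- vector("list", n)
    cortFrac <- deepFrac <- numeric(n)
    if (is.null(template$maskProto))
        template$maskProto <- .maskProto(template$grid)
    for (s in seq_len(n)) {
        ## per-subject centre bias: same family for both methylation groups
        pDeep <- runif(1, 0.02, 0.5)
        pCtx <- (1 - pDeep) * runif(1, 0.35, 0.95)
        bias <- c(cortex = pCtx, white_matter = 1 - pDeep - pCtx, deep_grey = pDeep)
        les <- generateLesion(template, bias, coreVol[s], oedVol[s],
                              subjectId = ids[s], hemisphere = hemisphere[s])
        coreMasks[[s]] <- les$core
        oedMasks[[s]] <- les$oedema
        globMasks[[s]] <- .fastMask(template$maskProto,
                                    pmax(les$core@values, les$oedema@values),
                                    "global", ids[s])
        pr <- compartmentOverlap(les$core, template$tissue)
        cortFrac[s] <- pr$fraction_of_lesion[pr$tissue_class == "cortex"]
        deepFrac[s] <- pr$fraction_of_lesion[pr$tissue_class == "deep_grey"]
    }
    names(coreMasks) <- names(oedMasks) <- names(globMasks) <- ids

    pct <- rep(NA_real_, n)
    mIdx <- which(status == "methylated")
    quantIdx <- sort(sample(mIdx, spec$nQuantified))
    cf <- cortFrac[quantIdx]
    r <- spec$plantedRCortex
    sdCf <- sd(cf)
    b <- r * spec$methylationSd / sdCf
    noiseSd <- spec$methylationSd * sqrt(1 - r^2)
    raw <- spec$methylationMean + b * (cf - mean(cf)) +
           rnorm(length(cf), 0, noiseSd)
    clipped <- pmin(100, pmax(spec$methylationFloor, raw))
    pct[quantIdx] <- round(clipped, 1)
    uIdx <- which(status == "unmethylated")
    pct[uIdx] <- round(runif(length(uIdx), 0, spec$methylationFloor - 0.1), 1)

    manifest <- data.frame(
        subject_id = ids, age = age, sex = sex, hemisphere = hemisphere,
        methylation_pct = pct, methylation_status = status,
        core_volume = vapply(coreMasks, maskVolumeMl, numeric(1)),
        oedema_volume = vapply(oedMasks, maskVolumeMl, numeric(1)),
        global_volume = vapply(globMasks, maskVolumeMl, numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)

    plantInfo <- list(
        achieved_r_cortex_preclip = cor(raw, cf),
        achieved_r_cortex = cor(pct[quantIdx], cortFrac[quantIdx]),
        achieved_r_deep = cor(pct[quantIdx], deepFrac[quantIdx]),
        clipped_fraction = mean(raw < spec$methylationFloor | raw > 100))
    structure(list(manifest = manifest,
                   masks = list(core = coreMasks, oedema = oedMasks,
                                global = globMasks),
                   template = template, spec = spec, plantInfo = plantInfo),
              class = "gbmCohort")
}

#' Generate a matched null cohort (methylation permuted against lesions)
#'
#' Generates the cohort for `seed` exactly as [generateCohort()] would (the
#' lesion set is identical to the matched non-null cohort with the same
#' seed), then permutes the methylation percentage and status jointly across
#' subjects, severing any location-methylation association by construction.
#'
#' @param spec a [syntheticCohortSpec()].
#' @param seed overrides `spec$seed` when given.
#' @param template optionally reuse an existing `gbmTemplate`.
#' @return A `gbmCohort` (see [generateCohort()]).
#' @export
generateNullCohort <- function(spec = syntheticCohortSpec(), seed = NULL,
                               template = NULL) {
    if (!is.null(seed)) spec$seed <- as.integer(seed)
    ch <- generateCohort(spec, template = template)
    perm <- sample.int(nrow(ch$manifest))
    ch$manifest$methylation_pct <- ch$manifest$methylation_pct[perm]
    ch$manifest$methylation_status <- ch$manifest$methylation_status[perm]
    ch$plantInfo <- NULL
    ch
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes the core/oedema masks as NIfTI, the four atlases as NIfTI + TSV
#' label tables, and the cohort manifest as TSV, under a self-describing
#' directory layout consumable by [runFullAnalysis()] and the command-line
#' interface.
#'
#' @param cohort a `gbmCohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "atlases"), showWarnings = FALSE)
    man <- cohort$manifest
    corePaths <- file.path("masks", paste0(man$subject_id, "_core.nii.gz"))
    oedPaths <- file.path("masks", paste0(man$subject_id, "_oedema.nii.gz"))
    for (s in seq_len(nrow(man))) {
        writeNiftiVolume(cohort$masks$core[[s]], file.path(dir, corePaths[s]))
        writeNiftiVolume(cohort$masks$oedema[[s]], file.path(dir, oedPaths[s]))
    }
    man$core_mask <- corePaths
    man$oedema_mask <- oedPaths
    utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in c("lobes", "tissue", "gmn", "wmn")) {
        writeNiftiVolume(cohort$template[[nm]],
                         file.path(dir, "atlases", paste0(nm, ".nii.gz")))
        writeAtlasTable(cohort$template[[nm]],
                        file.path(dir, "atlases", paste0(nm, ".tsv")))
    }
    writeNiftiVolume(array(as.numeric(cohort$template$brain),
                           dim = gridDims(cohort$template$grid)),
                     file.path(dir, "atlases", "brain.nii.gz"),
                     grid = cohort$template$grid)
    invisible(list(manifest = file.path(dir, "manifest.tsv"),
                   atlases = file.path(dir, "atlases")))
}
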