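## Lesion-atlas overlap quantification: lobar involvement with the 250-voxel
## rule, tissue-compartment volumes/fractions, within-tissue network ratios,
## and group frequency maps. Overlap is computed on core masks by default,
## matching the cohort analysis; other compartments can be passed explicitly.

.checkOverlapGrids <- function(mask, atlas) {
    if (!checkSameGrid(mask@grid, atlas@grid))
        stop("mask and atlas are on different grids")
}

## Per-label overlap voxel counts for one mask: named integer vector covering
## every label in the atlas table (zero where no overlap).
.overlapCounts <- function(mask, atlas) {
    lab <- atlas@labels[mask@values == 1]
    lab <- lab[lab != 0L]
    tab <- atlas@table
    counts <- setNames(integer(nrow(tab)), as.character(tab$label_id))
    if (length(lab)) {
        t0 <- table(lab)
        counts[names(t0)] <- as.integer(t0)
    }
    setNames(as.integer(counts), tab$region_name)
}

#' Lobes involved by a lesion (250-voxel rule)
#'
#' A lobe counts as involved when the lesion overlaps at least `minVoxels`
#' voxels of its label ("at least 250 voxels", read inclusively).
#'
#' @param mask a [LesionMask-class] (core, by convention).
#' @param lobes a [LabelAtlas-class] with tissue class `lobe`.
#' @param minVoxels inclusive overlap threshold (default 250).
#' @return Character vector of involved lobe names (possibly empty).
#' @export
lobarInvolvement <- function(mask, lobes, minVoxels = 250) {
    .checkOverlapGrids(mask, lobes)
    counts <- .overlapCounts(mask, lobes)
    names(counts)[counts >= minVoxels]
}

#' Tissue-compartment overlap profile
#'
#' For each tissue compartment (cortex, white matter, deep grey nuclei):
#' overlap voxel count, overlap volume in mL, and the fraction of the lesion
#' falling in that compartment. Fractions need not sum to 1 — lesion voxels
#' may fall outside all three compartments. For an empty lesion the fractions
#' are undefined and returned as `NA` (never coerced to 0).
#'
#' @param mask a [LesionMask-class].
#' @param tissue a [LabelAtlas-class] whose tissue classes include
#'   `cortex`, `white_matter` and `deep_grey`.
#' @return data.frame with columns `subject_id`, `tissue_class`,
#'   `overlap_voxels`, `overlap_ml`, `fraction_of_lesion`.
#' @export
compartmentOverlap <- function(mask, tissue) {
    .checkOverlapGrids(mask, tissue)
    classes <- c("cortex", "white_matter", "deep_grey")
    if (!all(classes %in% tissue@table$tissue_class))
        stop("tissue atlas must contain cortex, white_matter and deep_grey labels")
    counts <- .overlapCounts(mask, tissue)
    byClass <- vapply(classes, function(cl) {
        sum(counts[tissue@table$region_name[tissue@table$tissue_class == cl]])
    }, numeric(1))
    nles <- sum(mask@values)
    vv <- voxelVolume(mask@grid)
    data.frame(subject_id = mask@subjectId,
               tissue_class = classes,
               overlap_voxels = as.integer(byClass),
               overlap_ml = byClass * vv / 1000,
               fraction_of_lesion = if (nles > 0) byClass / nles else rep(NA_real_, 3),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-tissue functional-network overlap ratios
#'
#' For each network of one parcellation family (grey-matter or white-matter
#' networks), the ratio of lesion voxels inside that network to lesion voxels
#' inside the union of all networks of the same family. Defined ratios sum to
#' 1; when the lesion misses every network of the family all ratios are `NA`.
#'
#' @param mask a [LesionMask-class].
#' @param networks a [LabelAtlas-class] whose labels all share one tissue
#'   class (`gm_network` or `wm_network`).
#' @return data.frame with columns `subject_id`, `region_name`,
#'   `tissue_class`, `overlap_voxels`, `overlap_ml`, `within_tissue_ratio`.
#' @export
networkOverlapRatio <- function(mask, networks) {
    .checkOverlapGrids(mask, networks)
    tc <- unique(networks@table$tissue_class)
    if (length(tc) != 1L || !tc %in% c("gm_network", "wm_network"))
        stop("network atlas must hold a single gm_network or wm_network family")
    counts <- .overlapCounts(mask, networks)
    denom <- sum(counts)
    vv <- voxelVolume(mask@grid)
    data.frame(subject_id = mask@subjectId,
               region_name = names(counts),
               tissue_class = tc,
               overlap_voxels = as.integer(counts),
               overlap_ml = counts * vv / 1000,
               within_tissue_ratio = if (denom > 0) as.numeric(counts) / denom
                                     else rep(NA_real_, length(counts)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Group lesion frequency map
#'
#' Voxel-wise count of subjects whose lesion covers each voxel. The display
#' map ([displayCounts()]) zeroes voxels covered by fewer than
#' `displayThreshold` subjects (show only regions overlapped by at least two
#' lesions); the raw counts are retained in the object.
#'
#' @param masks list of [LesionMask-class] objects on one grid.
#' @param displayThreshold minimum count kept in the display map (default 2).
#' @param groupLabel free-text group description.
#' @return A [FrequencyMap-class].
#' @export
frequencyMap <- function(masks, displayThreshold = 2, groupLabel = "") {
    if (!length(masks)) stop("empty mask list")
    g <- masks[[1]]@grid
    counts <- array(0L, dim = g@dims)
    for (m in masks) {
        if (!checkSameGrid(m@grid, g)) stop("masks are on different grids")
        counts <- counts + as.integer(m@values)
    }
    new("FrequencyMap", grid = g, counts = counts, groupLabel = groupLabel,
        displayThreshold = as.integer(displayThreshold),
        nSubjects = length(masks))
}

#' Cohort overlap tables
#'
#' Applies one overlap measure to every subject and assembles the wide
#' per-cohort table (rows = subjects, columns = regions) written as TSV by
#' the pipeline.
#'
#' @param masks named list of [LesionMask-class] (names = subject ids).
#' @param atlas a [LabelAtlas-class].
#' @param measure `"fraction"` (compartment fraction-of-lesion),
#'   `"ratio"` (within-tissue network ratio) or `"voxels"`.
#' @return data.frame, one row per subject; first column `subject_id`.
#' @export
overlapTable <- function(masks, atlas, measure = c("fraction", "ratio", "voxels")) {
    measure <- match.arg(measure)
    rows <- lapply(masks, function(m) {
        if (measure == "fraction") {
            pr <- compartmentOverlap(m, atlas)
            setNames(pr$fraction_of_lesion, pr$tissue_class)
        } else if (measure == "ratio") {
            pr <- networkOverlapRatio(m, atlas)
            setNames(pr$within_tissue_ratio, pr$region_name)
        } else {
            .overlapCounts(m, atlas)
        }
    })
    out <- as.data.frame(do.call(rbind, rows))
    cbind(subject_id = vapply(masks, subjectId, character(1)), out,
          stringsAsFactors = FALSE, row.names = NULL)
}
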