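#' @import methods
#' @importFrom stats median pt pf pchisq cor sd rnorm runif quantile complete.cases setNames
#' @importFrom utils combn
#' @useDynLib gbmtopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ImageGrid: sampling grid of a template-space volume
#'
#' Describes the discrete grid every image in an analysis must share: the
#' array dimensions and the 4x4 voxel-to-world affine (mm, NIfTI convention,
#' zero-based voxel indices). The voxel volume in mm^3 is the absolute
#' determinant of the affine's upper-left 3x3 block; it is the unit that every
#' downstream volume (mL) and overlap statistic is built on.
#'
#' @slot dims integer(3), array dimensions (all >= 1).
#' @slot affine 4x4 numeric voxel-to-world transform; the upper-left 3x3
#'   block must be invertible.
#'
#' @seealso [voxelVolume()], [checkSameGrid()]
#' @export
setClass("ImageGrid", representation(dims = "integer", affine = "matrix"))

setValidity("ImageGrid", function(object) {
    msgs <- character()
    if (length(object@dims) != 3L || any(is.na(object@dims)) || any(object@dims < 1L))
        msgs <- c(msgs, "dims must be three integers >= 1")
    if (!all(dim(object@affine) == c(4L, 4L)))
        msgs <- c(msgs, "affine must be a 4x4 matrix")
    else {
        d <- det(object@affine[1:3, 1:3])
        if (!is.finite(d) || abs(d) < .Machine$double.eps)
            msgs <- c(msgs, "affine upper-left 3x3 block must be invertible")
    }
    if (length(msgs)) msgs else TRUE
})

#' LesionMask: one subject's binary lesion occupancy
#'
#' A binary 3D mask on an [ImageGrid-class], tagged with the tumour
#' compartment it delineates: the contrast-enhancing/non-enhancing core
#' (with necrosis), the surrounding oedema, or their union (`global`).
#'
#' @slot grid the [ImageGrid-class] the mask lives on.
#' @slot values 3D numeric array of 0/1 voxel occupancies.
#' @slot compartment one of `"core"`, `"oedema"`, `"global"`.
#' @slot subjectId subject identifier.
#'
#' @seealso [readMask()], [maskVolumeMl()], [flipLateral()]
#' @export
setClass("LesionMask", representation(grid = "ImageGrid", values = "array",
                                      compartment = "character", subjectId = "character"))

setValidity("LesionMask", function(object) {
    msgs <- character()
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
        msgs <- c(msgs, "values dimensions must equal grid dims")
    v <- object@values
    if (any(is.na(v)) || !all(v == 0 | v == 1))
        msgs <- c(msgs, "mask values must be binary (0/1)")
    if (!object@compartment %in% c("core", "oedema", "global"))
        msgs <- c(msgs, "compartment must be core, oedema or global")
    if (length(msgs)) msgs else TRUE
})

#' LabelAtlas: integer-labelled parcellation with a label table
#'
#' A 3D integer label volume (0 = background) plus a table mapping each label
#' to a region name and a tissue class. One atlas holds one mutually exclusive
#' parcellation: lobes, tissue compartments (cortex / white matter / deep grey
#' nuclei), grey-matter functional networks, or white-matter functional
#' networks.
#'
#' @slot grid the [ImageGrid-class].
#' @slot labels 3D integer array of region labels.
#' @slot table data.frame with columns `label_id`, `region_name`,
#'   `tissue_class`; tissue classes are drawn from
#'   `lobe`, `cortex`, `white_matter`, `deep_grey`, `gm_network`, `wm_network`.
#'
#' @seealso [readAtlas()], [lobarInvolvement()], [compartmentOverlap()]
#' @export
setClass("LabelAtlas", representation(grid = "ImageGrid", labels = "array",
                                      table = "data.frame"))

.tissueClasses <- c("lobe", "cortex", "white_matter", "deep_grey",
                    "gm_network", "wm_network")

setValidity("LabelAtlas", function(object) {
    msgs <- character()
    if (!identical(dim(object@labels), as.integer(object@grid@dims)))
        msgs <- c(msgs, "labels dimensions must equal grid dims")
    tab <- object@table
    need <- c("label_id", "region_name", "tissue_class")
    if (!all(need %in% names(tab)))
        return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(tab$label_id))
        msgs <- c(msgs, "duplicate label_id in table")
    if (!all(tab$tissue_class %in% .tissueClasses))
        msgs <- c(msgs, "unknown tissue_class in table")
    present <- unique(as.integer(object@labels))
    present <- present[present != 0L]
    missing <- setdiff(present, tab$label_id)
    if (length(missing))
        msgs <- c(msgs, sprintf("labels present in volume but absent from table: %s",
                                paste(missing, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' FrequencyMap: voxel-wise lesion overlap count over a group
#'
#' Voxel-wise count of subjects whose lesion covers each voxel, with a display
#' threshold (voxels covered by fewer subjects are zeroed in the display map,
#' mirroring the convention of showing only regions overlapped by at least two
#' lesions).
#'
#' @slot grid the [ImageGrid-class].
#' @slot counts 3D integer array of overlap counts.
#' @slot groupLabel description of the group, e.g. `"methylated"`.
#' @slot displayThreshold minimum count retained by [displayCounts()].
#' @slot nSubjects number of masks summed.
#'
#' @seealso [frequencyMap()]
#' @export
setClass("FrequencyMap", representation(grid = "ImageGrid", counts = "array",
                                        groupLabel = "character",
                                        displayThreshold = "integer",
                                        nSubjects = "integer"))

setValidity("FrequencyMap", function(object) {
    msgs <- character()
    if (!identical(dim(object@counts), as.integer(object@grid@dims)))
        msgs <- c(msgs, "counts dimensions must equal grid dims")
    if (any(object@counts < 0) || any(object@counts > object@nSubjects))
        msgs <- c(msgs, "counts must lie in [0, nSubjects]")
    if (length(msgs)) msgs else TRUE
})

#' VoxelwiseResult: mass-univariate lesion-mapping output
#'
#' Holds the observed t-map, parametric uncorrected p-map and max-statistic
#' permutation FWE-corrected p-map of one voxel-wise analysis, together with
#' the analysis mask (voxels entering the test), the permutation settings and
#' the null distribution of the maximum statistic. Maps are `NA` outside the
#' analysis mask.
#'
#' @slot grid the [ImageGrid-class].
#' @slot tMap,pUncorrected,pFwe 3D numeric arrays (`NA` outside the mask).
#' @slot analysisMask 3D 0/1 array of voxels entering the test.
#' @slot nPermutations number of permutations used.
#' @slot seed integer seed the permutation stream was started from.
#' @slot tails `"two"` (max |t|) or `"one"` (max t).
#' @slot nullMax numeric vector, the permutation null of the max statistic.
#' @slot nSubjects number of subjects analysed.
#' @slot exact TRUE when the permutation space was exhaustively enumerated.
#'
#' @seealso [permutationFwe()]
#' @export
setClass("VoxelwiseResult", representation(grid = "ImageGrid", tMap = "array",
                                           pUncorrected = "array", pFwe = "array",
                                           analysisMask = "array",
                                           nPermutations = "integer", seed = "integer",
                                           tails = "character", nullMax = "numeric",
                                           nSubjects = "integer", exact = "logical"))

setValidity("VoxelwiseResult", function(object) {
    d <- as.integer(object@grid@dims)
    for (s in c("tMap", "pUncorrected", "pFwe", "analysisMask"))
        if (!identical(dim(slot(object, s)), d))
            return(sprintf("%s dimensions must equal grid dims", s))
    pf <- object@pFwe[object@analysisMask == 1]
    if (length(pf) && (any(pf < 1 / (object@nPermutations + 1) - 1e-12) || any(pf > 1 + 1e-12)))
        return("pFwe must lie in [1/(nPermutations+1), 1] inside the mask")
    TRUE
})

## ---- show methods ----

setMethod("show", "ImageGrid", function(object) {
    cat(sprintf("ImageGrid: %s voxels, voxel volume %.3f mm^3\n",
                paste(object@dims, collapse = " x "), voxelVolume(object)))
})

setMethod("show", "LesionMask", function(object) {
    cat(sprintf("LesionMask '%s' (%s): %d lesioned voxels, %.2f mL on %s grid\n",
                object@subjectId, object@compartment, sum(object@values),
                maskVolumeMl(object), paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "LabelAtlas", function(object) {
    cat(sprintf("LabelAtlas: %d regions (%s) on %s grid\n",
                nrow(object@table),
                paste(unique(object@table$tissue_class), collapse = ", "),
                paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "FrequencyMap", function(object) {
    cat(sprintf("FrequencyMap '%s': n = %d subjects, max count %d, display threshold %d\n",
                object@groupLabel, object@nSubjects, max(object@counts),
                object@displayThreshold))
})

setMethod("show", "VoxelwiseResult", function(object) {
    nv <- sum(object@analysisMask)
    nsig <- sum(object@pFwe[object@analysisMask == 1] <= 0.05)
    cat(sprintf(paste0("VoxelwiseResult: %d voxels analysed, n = %d subjects, ",
                       "%d permutations (%s), %d voxels FWE-significant at 0.05\n"),
                nv, object@nSubjects, object@nPermutations,
                if (object@exact) "exact" else "random", nsig))
})
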