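## NIfTI input/output, grid compatibility, lateral flipping, volumes.
## All images in one analysis must share a single template grid; the package
## refuses mismatched grids rather than resampling silently, because
## nearest-neighbour resampling changes voxel counts — the unit every
## downstream statistic is expressed in. resampleNearest() is the explicit
## opt-in escape hatch.

#' Construct an ImageGrid
#'
#' @param dims integer(3) array dimensions.
#' @param affine 4x4 voxel-to-world matrix (mm, zero-based voxel indices).
#'   Defaults to an isotropic grid centred at the world origin.
#' @param voxelSizeMm isotropic voxel size used when `affine` is missing.
#' @return An [ImageGrid-class].
#' @examples
#' g <- imageGridCreate(c(10L, 10L, 10L), voxelSizeMm = 2)
#' voxelVolume(g)  # 8 mm^3
#' @export
imageGridCreate <- function(dims, affine = NULL, voxelSizeMm = 1) {
    dims <- as.integer(dims)
    if (is.null(affine)) {
        affine <- diag(c(rep(voxelSizeMm, 3), 1))
        affine[1:3, 4] <- -voxelSizeMm * (dims - 1) / 2
    }
    new("ImageGrid", dims = dims, affine = affine)
}

#' Construct a LesionMask from an array
#'
#' Values are binarized with the fixed 0.5 rule (any value > 0.5 becomes 1).
#'
#' @param values 3D array.
#' @param grid an [ImageGrid-class] (defaults to a unit grid of matching dims).
#' @param compartment `"core"`, `"oedema"` or `"global"`.
#' @param subjectId subject identifier.
#' @return A [LesionMask-class].
#' @export
lesionMask <- function(values, grid = NULL, compartment = "core", subjectId = "") {
    if (is.null(grid)) grid <- imageGridCreate(dim(values))
    v <- array(as.numeric(values > 0.5), dim = dim(values))
    new("LesionMask", grid = grid, values = v, compartment = compartment,
        subjectId = subjectId)
}

#' Construct a LabelAtlas from an array and a label table
#'
#' @param labels 3D integer array (0 = background).
#' @param table data.frame with `label_id`, `region_name`, `tissue_class`.
#' @param grid an [ImageGrid-class] (defaults to a unit grid).
#' @return A [LabelAtlas-class].
#' @export
labelAtlas <- function(labels, table, grid = NULL) {
    if (is.null(grid)) grid <- imageGridCreate(dim(labels))
    storage.mode(labels) <- "integer"
    table$label_id <- as.integer(table$label_id)
    table$region_name <- as.character(table$region_name)
    table$tissue_class <- as.character(table$tissue_class)
    new("LabelAtlas", grid = grid, labels = labels, table = table)
}

.gridFromNifti <- function(img) {
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    aff <- matrix(as.numeric(aff), 4L, 4L)
    imageGridCreate(dim(img), affine = aff)
}

.niftiFromArray <- function(arr, grid) {
    img <- RNifti::asNifti(arr)
    sp <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
    RNifti::pixdim(img) <- sp
    RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
}

#' Read a binary lesion mask from NIfTI
#'
#' Reads a 3D NIfTI volume, binarizes it with the 0.5 rule and, when a
#' reference grid is supplied, verifies the file's grid matches it (no silent
#' resampling).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param gridRef optional [ImageGrid-class] the mask must match.
#' @param compartment,subjectId metadata recorded on the mask.
#' @return A [LesionMask-class].
#' @export
readMask <- function(path, gridRef = NULL, compartment = "core", subjectId = "") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
        stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
    grid <- .gridFromNifti(img)
    if (!is.null(gridRef) && !checkSameGrid(grid, gridRef))
        stop("grid mismatch between ", path, " and the reference grid; ",
             "use resampleNearest() explicitly if resampling is intended")
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    lesionMask(arr, grid = if (is.null(gridRef)) grid else gridRef,
               compartment = compartment, subjectId = subjectId)
}

#' Write a mask, atlas or statistical map as NIfTI
#'
#' @param x a [LesionMask-class], [LabelAtlas-class], [FrequencyMap-class],
#'   or a plain 3D array (then `grid` is required).
#' @param path output `.nii` / `.nii.gz` path.
#' @param grid [ImageGrid-class] for plain arrays.
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(x, path, grid = NULL) {
    if (is(x, "LesionMask")) { arr <- x@values; grid <- x@grid }
    else if (is(x, "LabelAtlas")) { arr <- x@labels; grid <- x@grid }
    else if (is(x, "FrequencyMap")) { arr <- x@counts; grid <- x@grid }
    else { arr <- x; if (is.null(grid)) stop("grid required for plain arrays") }
    RNifti::writeNifti(.niftiFromArray(arr, grid), path)
    invisible(path)
}

#' Read a label atlas (NIfTI volume + TSV label table)
#'
#' The table is a three-column TSV: `label_id`, `region_name`, `tissue_class`.
#'
#' @param volumePath NIfTI integer label volume.
#' @param tablePath TSV label table.
#' @param gridRef optional reference [ImageGrid-class] to enforce.
#' @return A [LabelAtlas-class].
#' @export
readAtlas <- function(volumePath, tablePath, gridRef = NULL) {
    img <- RNifti::readNifti(volumePath)
    if (length(dim(img)) != 3L) stop("expected a 3D label volume: ", volumePath)
    grid <- .gridFromNifti(img)
    if (!is.null(gridRef) && !checkSameGrid(grid, gridRef))
        stop("grid mismatch between ", volumePath, " and the reference grid")
    tab <- utils::read.delim(tablePath, stringsAsFactors = FALSE)
    arr <- round(as.array(img))
    attributes(arr) <- list(dim = dim(arr))
    labelAtlas(arr, tab, grid = if (is.null(gridRef)) grid else gridRef)
}

#' Write an atlas label table as TSV
#' @param atlas a [LabelAtlas-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAtlasTable <- function(atlas, path) {
    utils::write.table(atlas@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Compare two grids for compatibility
#'
#' Grids match when the dimensions are equal and the affines agree
#' element-wise within an absolute tolerance.
#'
#' @param a,b [ImageGrid-class] objects.
#' @param tol absolute tolerance in mm (default 1e-4).
#' @return TRUE or FALSE.
#' @export
checkSameGrid <- function(a, b, tol = 1e-4) {
    identical(a@dims, b@dims) && all(abs(a@affine - b@affine) <= tol)
}

#' Lesion volume in millilitres
#'
#' `lesioned voxel count * voxel volume (mm^3) / 1000`.
#'
#' @param mask a [LesionMask-class].
#' @return Volume in mL.
#' @examples
#' m <- lesionMask(array(1, c(10, 10, 10)), imageGridCreate(rep(10L, 3), voxelSizeMm = 1))
#' maskVolumeMl(m)  # 1 mL
#' @export
maskVolumeMl <- function(mask) {
    sum(mask@values) * voxelVolume(mask@grid) / 1000
}

## Which voxel axis carries the world left-right (x) direction: the column of
## the affine's 3x3 block with the largest |x| component.
.lrAxis <- function(grid) which.max(abs(grid@affine[1, 1:3]))

## World x coordinate of a zero-based voxel index vector along all axes.
.worldX <- function(grid, idx0) {
    drop(grid@affine[1, 1:3] %*% idx0) + grid@affine[1, 4]
}

#' Reflect a lesion mask about the mid-sagittal plane
#'
#' `mirror` always reflects about the template's mid-sagittal voxel plane
#' (index i -> N + 1 - i along the left-right axis, taken as the voxel axis
#' with the dominant world-x direction). `unify_left` / `unify_right` reflect
#' only when the lesion's centre of mass lies in the opposite hemisphere;
#' masks already on the target side are returned unchanged. A centre of mass
#' exactly on the midline is treated as already unified (a message is
#' emitted). Used to pool left- and right-sided lesions before voxel-wise
#' analysis, effectively doubling the lesion sample the maps draw on.
#'
#' @param mask a [LesionMask-class].
#' @param mode `"mirror"`, `"unify_left"` or `"unify_right"`.
#' @return A [LesionMask-class] on the same grid.
#' @export
flipLateral <- function(mask, mode = c("mirror", "unify_left", "unify_right")) {
    mode <- match.arg(mode)
    ax <- .lrAxis(mask@grid)
    doFlip <- function(arr) {
        idx <- rep(list(quote(expr = )), 3)
        idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
        do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
    if (mode == "mirror") {
        out <- mask
        out@values <- doFlip(mask@values)
        return(out)
    }
    w <- which(mask@values == 1)
    if (!length(w)) return(mask)
    ijk <- arrayInd(w, dim(mask@values))
    com0 <- colMeans(ijk) - 1          # zero-based voxel centre of mass
    mid0 <- (mask@grid@dims - 1) / 2
    dx <- .worldX(mask@grid, com0) - .worldX(mask@grid, mid0)
    if (abs(dx) < 1e-9) {
        message("lesion centre of mass on the midline; treated as already unified (",
                mask@subjectId, ")")
        return(mask)
    }
    onRight <- dx > 0                  # +x is world right
    needFlip <- if (mode == "unify_left") onRight else !onRight
    if (!needFlip) return(mask)
    out <- mask
    out@values <- doFlip(mask@values)
    out
}

#' Nearest-neighbour resampling onto a reference grid (explicit opt-in)
#'
#' Maps each target voxel centre through the two affines and takes the value
#' of the nearest source voxel (0 outside the source field of view). Changes
#' voxel counts; never applied implicitly.
#'
#' @param mask a [LesionMask-class].
#' @param gridRef target [ImageGrid-class].
#' @return A [LesionMask-class] on `gridRef`.
#' @export
resampleNearest <- function(mask, gridRef) {
    src <- mask@grid
    d <- gridRef@dims
    tgt <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                                 k = seq_len(d[3]) - 1))
    world <- cbind(tgt, 1) %*% t(gridRef@affine)
    srcIdx <- world %*% t(solve(src@affine))
    srcIdx <- round(srcIdx[, 1:3])
    ok <- srcIdx[, 1] >= 0 & srcIdx[, 1] < src@dims[1] &
          srcIdx[, 2] >= 0 & srcIdx[, 2] < src@dims[2] &
          srcIdx[, 3] >= 0 & srcIdx[, 3] < src@dims[3]
    vals <- numeric(nrow(tgt))
    lin <- srcIdx[ok, 1] + src@dims[1] * (srcIdx[ok, 2] + src@dims[2] * srcIdx[ok, 3]) + 1
    vals[ok] <- mask@values[lin]
    lesionMask(array(vals, dim = d), grid = gridRef,
               compartment = mask@compartment, subjectId = mask@subjectId)
}

#' Combine core and oedema masks into the global compartment
#'
#' The global mask is the voxel-wise union of a subject's core and oedema.
#'
#' @param core,oedema [LesionMask-class] objects on one grid.
#' @return A [LesionMask-class] with compartment `"global"`.
#' @export
globalMask <- function(core, oedema) {
    if (!checkSameGrid(core@grid, oedema@grid)) stop("core/oedema grid mismatch")
    lesionMask(pmax(core@values, oedema@values), grid = core@grid,
               compartment = "global", subjectId = core@subjectId)
}
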