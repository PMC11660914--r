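#' Accessors for the imaging classes
#'
#' Small read-only accessors: `gridDims()` and `gridAffine()` expose the grid
#' geometry, `voxelVolume()` the voxel volume in mm^3 (|det| of the affine's
#' 3x3 block), `maskArray()` / `atlasLabels()` / `mapCounts()` the underlying
#' arrays, `subjectId()` and `compartment()` the mask metadata,
#' `labelTable()` the atlas label table, and `displayCounts()` the
#' threshold-zeroed frequency map.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value (or derived quantity).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))
#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname accessors
#' @export
setGeneric("mapCounts", function(x) standardGeneric("mapCounts"))
#' @rdname accessors
#' @export
setGeneric("displayCounts", function(x) standardGeneric("displayCounts"))
#' @rdname accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
#' @rdname accessors
#' @export
setGeneric("pFwe", function(x) standardGeneric("pFwe"))
#' @rdname accessors
#' @export
setGeneric("pUncorrected", function(x) standardGeneric("pUncorrected"))
#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname accessors
setMethod("imageGrid", "LesionMask", function(x) x@grid)
#' @rdname accessors
setMethod("imageGrid", "LabelAtlas", function(x) x@grid)
#' @rdname accessors
setMethod("imageGrid", "FrequencyMap", function(x) x@grid)
#' @rdname accessors
setMethod("imageGrid", "VoxelwiseResult", function(x) x@grid)

#' @rdname accessors
setMethod("gridDims", "ImageGrid", function(x) x@dims)
#' @rdname accessors
setMethod("gridAffine", "ImageGrid", function(x) x@affine)
#' @rdname accessors
setMethod("voxelVolume", "ImageGrid", function(x) abs(det(x@affine[1:3, 1:3])))
#' @rdname accessors
setMethod("voxelVolume", "LesionMask", function(x) voxelVolume(x@grid))

#' @rdname accessors
setMethod("maskArray", "LesionMask", function(x) x@values)
#' @rdname accessors
setMethod("subjectId", "LesionMask", function(x) x@subjectId)
#' @rdname accessors
setMethod("compartment", "LesionMask", function(x) x@compartment)

#' @rdname accessors
setMethod("atlasLabels", "LabelAtlas", function(x) x@labels)
#' @rdname accessors
setMethod("labelTable", "LabelAtlas", function(x) x@table)

#' @rdname accessors
setMethod("mapCounts", "FrequencyMap", function(x) x@counts)
#' @rdname accessors
setMethod("displayCounts", "FrequencyMap", function(x) {
    out <- x@counts
    out[out < x@displayThreshold] <- 0L
    out
})

#' @rdname accessors
setMethod("tMap", "VoxelwiseResult", function(x) x@tMap)
#' @rdname accessors
setMethod("pFwe", "VoxelwiseResult", function(x) x@pFwe)
#' @rdname accessors
setMethod("pUncorrected", "VoxelwiseResult", function(x) x@pUncorrected)
#' @rdname accessors
setMethod("analysisMask", "VoxelwiseResult", function(x) x@analysisMask)
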