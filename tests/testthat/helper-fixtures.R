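# In-code fixtures shared across test files. Everything is built
# programmatically; nothing is read from disk except NIfTI round-trips
# through tempfiles.

# tiny isotropic grid (1 mm voxels unless stated)
tinyGrid <- function(n = 10L, vs = 1) imageGridCreate(rep(as.integer(n), 3), voxelSizeMm = vs)

# mask with given 1-based voxel indices set
maskAt <- function(idx, n = 10L, vs = 1, compartment = "core", id = "s1") {
    a <- array(0, dim = rep(n, 3))
    a[idx] <- 1
    lesionMask(a, tinyGrid(n, vs), compartment = compartment, subjectId = id)
}

# toy tissue atlas: planes of cortex / white matter / deep grey along k
toyTissueAtlas <- function(n = 10L) {
    lab <- array(0L, dim = rep(n, 3))
    lab[, , 1:3] <- 1L   # cortex
    lab[, , 4:6] <- 2L   # white matter
    lab[, , 7] <- 3L     # deep grey
    labelAtlas(lab, data.frame(label_id = 1:3,
                               region_name = c("cortex", "white_matter", "deep_grey"),
                               tissue_class = c("cortex", "white_matter", "deep_grey")),
               tinyGrid(n))
}

toyNetworkAtlas <- function(n = 10L, tissue = "gm_network") {
    lab <- array(0L, dim = rep(n, 3))
    lab[, , 1:2] <- 1L
    lab[, , 3:4] <- 2L
    labelAtlas(lab, data.frame(label_id = 1:2,
                               region_name = c("netA", "netB"),
                               tissue_class = tissue),
               tinyGrid(n))
}

# small template + fixture cohort, computed once per test run
fixtureTemplate <- local({
    val <- NULL
    function() {
        if (is.null(val)) val <<- generateTemplate(c(24L, 24L, 24L), 4)
        val
    }
})

fixtureCohort <- local({
    val <- NULL
    function() {
        if (is.null(val))
            val <<- generateCohort(syntheticCohortSpec(preset = "fixtures", seed = 11))
        val
    }
})

# independent 6-connectivity component count (flood fill), used as an oracle
countComponents6 <- function(arr) {
    dims <- dim(arr)
    lab <- array(0L, dim = dims)
    nc <- 0L
    idxAll <- which(arr == 1)
    for (start in idxAll) {
        if (lab[start] > 0) next
        nc <- nc + 1L
        queue <- start
        lab[start] <- nc
        while (length(queue)) {
            cur <- queue[length(queue)]
            queue <- queue[-length(queue)]
            ijk <- arrayInd(cur, dims)
            for (d in 1:3) for (s in c(-1L, 1L)) {
                nb <- ijk
                nb[d] <- nb[d] + s
                if (nb[d] < 1 || nb[d] > dims[d]) next
                lin <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
                if (arr[lin] == 1 && lab[lin] == 0) {
                    lab[lin] <- nc
                    queue <- c(queue, lin)
                }
            }
        }
    }
    nc
}
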