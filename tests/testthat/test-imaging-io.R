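test_that("NIfTI round-trip preserves binary masks and applies the 0.5 rule", {
    g <- tinyGrid(10, 2)
    # probabilistic values are binarized element-wise at 0.5
    probs <- array(0, dim = c(10, 10, 10))
    probs[1:5, 1, 1] <- c(0.2, 0.7, 0.49, 0.51, 1)
    f <- tempfile(fileext = ".nii.gz")
    writeNiftiVolume(probs, f, grid = g)
    m <- readMask(f, gridRef = g, subjectId = "p")
    expect_equal(maskArray(m), array(as.numeric(probs > 0.5), dim = dim(probs)))

    # empty and already-binary masks survive a write/read cycle untouched
    empty <- maskAt(integer(0))
    f2 <- tempfile(fileext = ".nii.gz")
    writeNiftiVolume(empty, f2)
    expect_equal(sum(maskArray(readMask(f2))), 0)

    m1 <- maskAt(c(1, 500, 999))
    f3 <- tempfile(fileext = ".nii.gz")
    writeNiftiVolume(m1, f3)
    back <- readMask(f3, gridRef = imageGrid(m1))
    expect_identical(maskArray(back), maskArray(m1))
    # binarization is idempotent: a second cycle reproduces the same array
    writeNiftiVolume(back, f3)
    expect_identical(maskArray(readMask(f3)), maskArray(m1))
})

test_that("grid checking refuses mismatches and respects tolerance", {
    a <- tinyGrid(10); b <- tinyGrid(10)
    expect_true(checkSameGrid(a, b))
    aff <- gridAffine(b); aff[1, 4] <- aff[1, 4] + 1
    shifted <- imageGridCreate(gridDims(b), affine = aff)
    expect_false(checkSameGrid(a, shifted))
    aff2 <- gridAffine(b); aff2[1, 4] <- aff2[1, 4] + 1e-6
    expect_true(checkSameGrid(a, imageGridCreate(gridDims(b), affine = aff2)))

    f <- tempfile(fileext = ".nii.gz")
    writeNiftiVolume(maskAt(1), f)
    expect_error(readMask(f, gridRef = shifted), "mismatch")
    # 4D input is rejected
    f4 <- tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), f4)
    expect_error(readMask(f4), "3D")
})

test_that("mask volume is count times voxel volume in mL and additive", {
    expect_equal(maskVolumeMl(maskAt(1:1000, n = 12, vs = 1)), 1.0)
    expect_equal(maskVolumeMl(maskAt(integer(0))), 0.0)
    expect_equal(maskVolumeMl(maskAt(1:500, n = 10, vs = 2)), 4.0)

    core <- maskAt(1:100, compartment = "core")
    oed <- maskAt(201:350, compartment = "oedema")
    glob <- globalMask(core, oed)
    expect_equal(maskVolumeMl(core) + maskVolumeMl(oed), maskVolumeMl(glob))
    expect_identical(compartment(glob), "global")
})

test_that("mirror flipping reflects indices about the mid-sagittal plane", {
    n <- 11
    m <- maskAt(integer(0), n = n)
    a <- array(0, dim = rep(n, 3)); a[3, 5, 7] <- 1
    m <- lesionMask(a, tinyGrid(n), subjectId = "f")
    flip <- flipLateral(m, "mirror")
    expect_equal(which(maskArray(flip) == 1),
                 which(array(seq_len(n^3), rep(n, 3)) ==
                       ((9 - 1) + n * ((5 - 1) + n * (7 - 1)) + 1)))
    # involution and exact count preservation
    expect_identical(maskArray(flipLateral(flip, "mirror")), maskArray(m))
    set.seed(5)
    big <- maskAt(sample(11^3, 300), n = 11)
    expect_equal(sum(maskArray(flipLateral(big, "mirror"))), 300)
})

test_that("unify modes flip only lesions on the opposite hemisphere", {
    n <- 11
    left <- maskAt(2, n = n)        # i = 2 < midline 6 -> world x negative
    right <- maskAt(10, n = n)
    expect_identical(maskArray(flipLateral(left, "unify_left")), maskArray(left))
    expect_identical(maskArray(flipLateral(right, "unify_left")),
                     maskArray(flipLateral(right, "mirror")))
    expect_identical(maskArray(flipLateral(right, "unify_right")), maskArray(right))
    # centre of mass exactly on the midline: treated as already unified
    mid <- maskAt(6, n = n)
    expect_message(out <- flipLateral(mid, "unify_left"), "midline")
    expect_identical(maskArray(out), maskArray(mid))
})

test_that("nearest-neighbour resampling is an identity on the same grid", {
    m <- maskAt(c(5, 250, 777))
    expect_identical(maskArray(resampleNearest(m, imageGrid(m))), maskArray(m))
})

test_that("atlas NIfTI + TSV round trip preserves labels and table", {
    atlas <- toyTissueAtlas()
    fv <- tempfile(fileext = ".nii.gz"); ft <- tempfile(fileext = ".tsv")
    writeNiftiVolume(atlas, fv)
    writeAtlasTable(atlas, ft)
    back <- readAtlas(fv, ft, gridRef = imageGrid(atlas))
    expect_identical(atlasLabels(back), atlasLabels(atlas))
    expect_identical(labelTable(back)$region_name, labelTable(atlas)$region_name)
})
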