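test_that("the synthetic template is mirror-symmetric with disjoint tissues", {
    tpl <- fixtureTemplate()
    mirror <- function(arr) arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
    expect_identical(mirror(tpl$brain), tpl$brain)
    for (nm in c("lobes", "tissue", "gmn", "wmn"))
        expect_identical(mirror(atlasLabels(tpl[[nm]])), atlasLabels(tpl[[nm]]))

    lab <- atlasLabels(tpl$tissue)
    # tissue classes are disjoint (one label per voxel) and cover the brain
    expect_true(all((lab > 0) == tpl$brain))

    # label histogram matches an independent per-voxel recount
    tab <- labelTable(tpl$gmn)
    counts <- table(factor(atlasLabels(tpl$gmn)[atlasLabels(tpl$gmn) > 0],
                           levels = tab$label_id))
    manual <- vapply(tab$label_id, function(id)
        sum(atlasLabels(tpl$gmn) == id), numeric(1))
    expect_equal(as.numeric(counts), manual)
    expect_true(all(manual > 0))
    expect_gte(nrow(labelTable(tpl$gmn)), 7)
    expect_gte(nrow(labelTable(tpl$wmn)), 4)
    expect_error(generateTemplate(c(8, 8, 8)), "too small")
})

test_that("grown lesions hit their target volume and stay coherent", {
    tpl <- fixtureTemplate()
    set.seed(91)
    for (i in 1:4) {
        les <- generateLesion(tpl, targetVolumeMl = 8, oedemaVolumeMl = 10,
                              subjectId = "g", hemisphere = "left")
        expect_lt(abs(maskVolumeMl(les$core) - 8) / 8, 0.10)
        # disjoint core and oedema; both inside the brain
        expect_equal(max(maskArray(les$core) + maskArray(les$oedema)), 1)
        expect_true(all(tpl$brain[maskArray(les$core) == 1]))
        expect_true(all(tpl$brain[maskArray(les$oedema) == 1]))
        # core is a single 6-connected component (flood-fill oracle)
        expect_equal(countComponents6(maskArray(les$core)), 1)
        expect_equal(countComponents6(pmax(maskArray(les$core),
                                           maskArray(les$oedema))), 1)
    }
})

test_that("cohort generation is reproducible and internally consistent", {
    ch <- fixtureCohort()
    spec <- ch$spec
    man <- ch$manifest
    expect_equal(nrow(man), spec$nSubjects)
    expect_equal(sum(man$methylation_status == "methylated"), spec$nMethylated)
    expect_equal(sum(!is.na(man$methylation_pct) &
                     man$methylation_status == "methylated"), spec$nQuantified)

    # stored status equals the >= 8% rule wherever a percentage exists
    has <- !is.na(man$methylation_pct)
    expect_identical(classifyMethylation(man$methylation_pct[has]),
                     man$methylation_status[has])
    # global volume bookkeeping
    expect_true(all(man$global_volume + 1e-9 >=
                    pmax(man$core_volume, man$oedema_volume)))

    # bit-reproducible with the same seed
    ch2 <- generateCohort(syntheticCohortSpec(preset = "fixtures", seed = 11))
    expect_identical(ch2$manifest, man)
    expect_identical(maskArray(ch2$masks$core[[1]]),
                     maskArray(ch$masks$core[[1]]))
})

test_that("cohort moments land near their targets on a full-size cohort", {
    ch <- generateCohort(syntheticCohortSpec(preset = "calibration", seed = 2))
    man <- ch$manifest
    q <- !is.na(man$methylation_pct) & man$methylation_status == "methylated"
    # three standard errors around the generating moments
    expect_lt(abs(mean(man$methylation_pct[q]) - 33.9), 3 * 18.3 / sqrt(41) + 2)
    expect_lt(abs(sd(man$methylation_pct[q]) - 18.3), 3 * 18.3 / sqrt(2 * 41) + 2)
    expect_lt(abs(mean(man$core_volume) - 43.2), 3 * 29.3 / sqrt(93) + 2)
    expect_lt(abs(mean(man$oedema_volume) - 54.8), 3 * 43.4 / sqrt(93) + 2)
    # planted correlation reported by the generator matches a recomputation
    tt <- overlapTable(ch$masks$core[which(q)], ch$template$tissue, "fraction")
    expect_equal(cor(man$methylation_pct[q], tt$cortex),
                 ch$plantInfo$achieved_r_cortex, tolerance = 1e-12)
})

test_that("the null cohort shares lesions but severs the methylation link", {
    spec <- syntheticCohortSpec(preset = "fixtures", seed = 23)
    ch <- generateCohort(spec)
    nul <- generateNullCohort(spec, seed = 23)
    expect_identical(maskArray(nul$masks$core[[2]]),
                     maskArray(ch$masks$core[[2]]))
    expect_setequal(nul$manifest$methylation_pct, ch$manifest$methylation_pct)
    expect_equal(sum(nul$manifest$methylation_status == "methylated"),
                 spec$nMethylated)
})

test_that("a cohort written to disk reloads identically", {
    ch <- fixtureCohort()
    dir <- file.path(tempdir(), "cohort-rt")
    writeCohort(ch, dir)
    back <- loadCohortDir(dir)
    expect_equal(back$manifest$subject_id, ch$manifest$subject_id)
    expect_equal(back$manifest$methylation_pct, ch$manifest$methylation_pct)
    for (s in seq_len(nrow(ch$manifest)))
        expect_identical(maskArray(back$masks$core[[s]]),
                         maskArray(ch$masks$core[[s]]))
    expect_identical(atlasLabels(back$template$gmn),
                     atlasLabels(ch$template$gmn))
})
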