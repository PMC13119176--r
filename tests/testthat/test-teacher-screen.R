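test_that("IoU matches area arithmetic", {
    a <- c(0.5, 0.5, 0.2, 0.2)
    expect_equal(boxIoU(a, a), 1)
    expect_equal(boxIoU(a, c(0.9, 0.9, 0.1, 0.1)), 0)
    # unit squares offset by half a side: intersection 1/2, union 3/2
    expect_equal(boxIoU(c(0.5, 0.5, 1, 1) / 2 + c(0.25, 0.25, 0, 0),
                        c(0.75, 0.5, 0.5, 0.5)), 1 / 3, tolerance = 1e-12)
    expect_equal(boxIoU(a, c(0.5, 0.5, 0, 0.2)), 0)   # degenerate box
    # symmetry
    b <- c(0.45, 0.55, 0.3, 0.1)
    expect_equal(boxIoU(a, b), boxIoU(b, a))
})

test_that("perfect and adversarial teachers produce the expected
           verdicts", {
    smp <- onePasteSample(32L)
    res <- screenSample(smp, oracleTeacher(), screeningConfig())
    expect_true(res@accepted)
    expect_identical(res@verdicts$reason, "ok")
    # strictest thresholds still accept a perfect oracle
    strict <- screeningConfig(confMin = 1, iouMin = 1)
    expect_true(screenSample(smp, oracleTeacher(), strict)@accepted)
    # never-detect teacher: rejected for poor localization
    bad <- screenSample(smp, oracleTeacher(detectionProb = 0))
    expect_false(bad@accepted)
    expect_identical(bad@verdicts$reason, "poor_localization")
    # screening never mutates the sample
    expect_identical(smp@image, onePasteSample(32L)@image)
    expect_error(screenSample(asAugmentedSample(flatImage(8L), .emptyAnn()),
                              oracleTeacher()), "no pasted boxes")
})

test_that("rejection reasons reflect the failing criterion", {
    smp <- onePasteSample(32L)
    low <- screenSample(smp, oracleTeacher(confBase = 0.1),
                        screeningConfig(confMin = 0.5))
    expect_identical(low@verdicts$reason, "low_confidence")
    wrongClass <- functionTeacher(function(image, truth) {
        d <- truth; d$class_id <- d$class_id + 1L; d$confidence <- 1
        d
    })
    mis <- screenSample(smp, wrongClass, screeningConfig())
    expect_identical(mis@verdicts$reason, "class_mismatch")
    expect_true(screenSample(smp, wrongClass,
        screeningConfig(requireClassMatch = FALSE))@accepted)
    occluded <- smp
    occluded@visibleFraction <- 0.2
    occ <- screenSample(occluded, oracleTeacher(),
                        screeningConfig(minVisibleFraction = 0.5))
    expect_identical(occ@verdicts$reason, "over_occluded")
})

test_that("acceptance rate under a partial-detection oracle is binomial", {
    smp <- onePasteSample(16L)
    set.seed(202)
    teacher <- oracleTeacher(detectionProb = 0.7)
    acc <- replicate(1000, screenSample(smp, teacher)@accepted)
    expect_lt(abs(mean(acc) - 0.7), 0.03)
})

test_that("batch screening partitions the input and tallies reasons", {
    ds <- generateDataset(smallFixtureSpec(seed = 29L))
    bank <- buildBank(extractInstances(ds), classNames(ds))
    res <- planAndAugment(ds, bank, augPolicy(targetCount = 8L), seed = 6L)
    expect_identical(screenBatch(list(), oracleTeacher())$summary$n_kept, 0L)
    all_ <- screenBatch(res$samples, oracleTeacher())
    expect_length(all_$kept, length(res$samples))
    expect_length(all_$rejected, 0L)
    set.seed(31)
    some <- screenBatch(res$samples, oracleTeacher(detectionProb = 0.5))
    expect_identical(length(some$kept) + length(some$rejected),
                     length(res$samples))
    nrej <- sum(unlist(some$summary[c("low_confidence", "poor_localization",
                                      "class_mismatch", "over_occluded")]))
    expect_identical(nrej, length(some$rejected))
    expect_identical(some$summary$n_rejected, length(some$rejected))
})

test_that("raising either threshold never grows the kept set", {
    ds <- generateDataset(smallFixtureSpec(seed = 37L))
    bank <- buildBank(extractInstances(ds), classNames(ds))
    res <- planAndAugment(ds, bank, augPolicy(targetCount = 8L), seed = 8L)
    noisy <- oracleTeacher(detectionProb = 0.9, confBase = 0.6,
                           confSd = 0.2, locNoise = 2)
    keptNames <- function(confMin, iouMin) {
        set.seed(404)  # same teacher draws for every threshold setting
        r <- screenBatch(res$samples, noisy,
                         screeningConfig(confMin = confMin, iouMin = iouMin))
        which(vapply(r$results, function(x) x@accepted, TRUE))
    }
    prev <- keptNames(0.25, 0.3)
    for (tau in c(0.4, 0.6, 0.8)) {
        k <- keptNames(tau, 0.3)
        expect_true(all(k %in% prev))
        prev <- k
    }
    prev <- keptNames(0.25, 0.3)
    for (theta in c(0.5, 0.7, 0.9)) {
        k <- keptNames(0.25, theta)
        expect_true(all(k %in% prev))
        prev <- k
    }
})
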