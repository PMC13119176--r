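test_that("class deficits follow the floor scheme", {
    expect_identical(unname(classDeficits(c(755, 2), 54)), c(0L, 52L))
    expect_identical(unname(classDeficits(c(100, 200, 300), 50)),
                     c(0L, 0L, 0L))
    expect_identical(unname(classDeficits(c(10, 5), c(20, 5))), c(10L, 0L))
    expect_error(classDeficits(c(10, 5), c(20, 5, 1)), "per class")
})

test_that("placement sampling is uniform over the frame including edges", {
    set.seed(55)
    n <- 10000L
    ctrs <- t(replicate(n, samplePlacement(c(0.01, 0.01))))
    ann <- data.frame(class_id = 0L, cx = ctrs[, 1], cy = ctrs[, 2],
                      w = 0.01, h = 0.01)
    h <- centerHistogram(annotationOnlyDataset(ann), bins = 4L)
    p <- 1 / 16
    bound <- 3 * sqrt(n * p * (1 - p)) / n + 0.003  # + band-edge truncation
    expect_true(max(abs(h - p)) <= bound)
})

test_that("placement respects forced and infeasible geometries", {
    expect_equal(unname(samplePlacement(c(1, 1))), c(0.5, 0.5))
    # frame tiled by existing boxes with zero tolerated overlap
    tiles <- expand.grid(cx = seq(0.125, 0.875, by = 0.25),
                         cy = seq(0.125, 0.875, by = 0.25))
    tiles <- data.frame(class_id = 0L, tiles, w = 0.25, h = 0.25)
    set.seed(1)
    expect_null(samplePlacement(c(0.2, 0.2), tiles, maxOverlapIoU = 0,
                                retryBudget = 100L))
    # placements keep the whole box inside and under the IoU cap
    set.seed(2)
    keep <- data.frame(class_id = 0L, cx = .5, cy = .5, w = .4, h = .4)
    for (k in 1:200) {
        ctr <- samplePlacement(c(0.3, 0.3), keep, maxOverlapIoU = 0.1)
        if (is.null(ctr)) next
        expect_gte(ctr[1], 0.15 - 1e-12); expect_lte(ctr[1], 0.85 + 1e-12)
        expect_lte(boxIoU(c(ctr, 0.3, 0.3), keep), 0.1 + 1e-12)
    }
})

test_that("hard paste changes exactly the pasted rectangle", {
    S <- 32L
    smp <- onePasteSample(S, donorValue = 0.9, blendMode = "hard")
    diffs <- which(smp@image != 0.2, arr.ind = TRUE)
    expect_identical(nrow(diffs), 8L * 8L * 3L)   # 64 px in 3 channels
    expect_true(all(smp@image[diffs] == 0.9))
    # new annotation matches the placement arithmetic
    expect_identical(nrow(smp@annotations), 1L)
    a <- smp@annotations[1, ]
    expect_equal(c(a$cx, a$cy), c(0.5, 0.5), tolerance = 1 / S)
    expect_equal(c(a$w, a$h), c(8 / S, 8 / S), tolerance = 1e-9)
    expect_identical(nrow(smp@provenance), 1L)
})

test_that("feathered paste keeps donor pixels where alpha is 1 and leaves
           originals alone", {
    S <- 48L
    bg <- asAugmentedSample(flatImage(S, 0.1),
                            data.frame(class_id = 0L, cx = .2, cy = .2,
                                       w = .1, h = .1))
    alpha <- matrix(0, 12, 12)
    alpha[4:9, 4:9] <- 1
    donor <- new("LesionInstance", pixels = array(0.8, c(12, 12, 3)),
                 alpha = alpha, classId = 1L,
                 source = list(item = "d", annIndex = 1L),
                 nativeScale = 12 / S)
    out <- pasteInstance(bg, donor, c(0.5, 0.5), 1, "feathered")
    # interior of the pasted region equals the donor
    ctr <- S / 2
    expect_true(all(out@image[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2), ]
                    == 0.8))
    # original annotation unchanged, one appended
    expect_identical(nrow(out@annotations), 2L)
    expect_equal(out@annotations[1, ], bg@annotations[1, ],
                 ignore_attr = TRUE)
    # recorded box is the alpha > 0.5 extent (6 px core)
    expect_equal(out@annotations$w[2], 6 / S, tolerance = 1.5 / S)
})

test_that("planner reaches per-class floors and lowers the imbalance
           ratio", {
    ds <- generateDataset(smallFixtureSpec(seed = 19L))
    bank <- buildBank(extractInstances(ds), classNames(ds))
    pol <- augPolicy(targetCount = 8L)
    res <- planAndAugment(ds, bank, pol, profile = NULL, seed = 4L)
    planned <- counts(res$planned)
    expect_true(all(planned >= 8L))
    expect_identical(sum(res$pastes),
                     sum(classDeficits(classDistribution(ds), 8L)))
    expect_lt(imbalanceRatio(res$planned),
              imbalanceRatio(classDistribution(ds)))
    # counts never decrease
    expect_true(all(planned >= counts(classDistribution(ds))))
    # emitted samples carry provenance for every pasted box and valid labels
    for (s in res$samples) {
        expect_true(validObject(s))
        expect_gte(nrow(s@provenance), 1L)
        expect_true(all(s@provenance$annIndex <= nrow(s@annotations)))
        orig <- s@annotations[setdiff(seq_len(nrow(s@annotations)),
                                      s@provenance$annIndex), , drop = FALSE]
        for (pi in s@provenance$annIndex) {
            pb <- s@annotations[pi, ]
            if (nrow(orig))
                for (oi in seq_len(nrow(orig)))
                    expect_lte(boxIoU(pb, orig[oi, ]), 0.1 + 1e-9)
        }
    }
})

test_that("planner is deterministic and degenerate targets are no-ops", {
    ds <- generateDataset(smallFixtureSpec(seed = 19L))
    bank <- buildBank(extractInstances(ds), classNames(ds))
    pol <- augPolicy(targetCount = 8L)
    r1 <- planAndAugment(ds, bank, pol, profile = envProfile(), seed = 9L)
    r2 <- planAndAugment(ds, bank, pol, profile = envProfile(), seed = 9L)
    expect_identical(lapply(r1$samples, function(s) s@annotations),
                     lapply(r2$samples, function(s) s@annotations))
    expect_identical(lapply(r1$samples, function(s) s@image),
                     lapply(r2$samples, function(s) s@image))
    # targets below every count: nothing to do
    r0 <- planAndAugment(ds, bank, augPolicy(targetCount = 1L), seed = 1L)
    expect_length(r0$samples, 0L)
    expect_identical(counts(r0$planned), counts(classDistribution(ds)))
})

test_that("deficit classes without donors are reported by name", {
    ds <- generateDataset(smallFixtureSpec(seed = 19L))
    bank <- buildBank(extractInstances(ds, classes = 0:3), classNames(ds))
    expect_error(planAndAugment(ds, bank, augPolicy(targetCount = 8L)),
                 "lesion_04")
})

test_that("effective coverage never drops after augmentation at any
           threshold up to the floor", {
    ds <- generateDataset(smallFixtureSpec(seed = 23L))
    bank <- buildBank(extractInstances(ds), classNames(ds))
    res <- planAndAugment(ds, bank, augPolicy(targetCount = 7L), seed = 2L)
    before <- classDistribution(ds)
    for (t in 0:7)
        expect_gte(effectiveCoverage(res$planned, t)$count,
                   effectiveCoverage(before, t)$count)
})
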