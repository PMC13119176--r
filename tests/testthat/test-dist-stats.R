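test_that("imbalance ratio matches the worked extremes and identities", {
    expect_equal(imbalanceRatio(c(755, 300, 120, 2)), 377.5)
    expect_equal(imbalanceRatio(c(5101, 1200, 54)), 5101 / 54,
                 tolerance = 1e-12)
    expect_equal(imbalanceRatio(rep(17, 8)), 1)
    expect_message(v <- imbalanceRatio(c(10, 0, 5)), "zero-count")
    expect_equal(v, 2)
    expect_error(suppressMessages(imbalanceRatio(c(0, 0))), "all counts")
})

test_that("log dispersion is the population sd of log counts and is
           scale-invariant", {
    expect_equal(logDispersion(rep(100, 5)), 0)
    expect_equal(logDispersion(c(10, 1000)), log(1000 / 10) / 2,
                 tolerance = 1e-12)
    expect_equal(logDispersion(c(10, 1000)), 2.302585, tolerance = 1e-6)
    # base change only rescales
    expect_equal(logDispersion(c(10, 1000), base = 10),
                 logDispersion(c(10, 1000)) / log(10), tolerance = 1e-12)
    set.seed(7)
    for (k in 1:20) {
        v <- sample(1:500, 12)
        expect_equal(logDispersion(v * sample(2:9, 1)), logDispersion(v),
                     tolerance = 1e-10)
    }
    expect_error(suppressMessages(logDispersion(c(5, 0))), "at least 2")
})

test_that("effective coverage and sample proportion match direct counting", {
    cnts <- c(rep(250, 17), rep(10, 13))       # 17 of 30 qualify at 200
    cov <- effectiveCoverage(cnts, 200)
    expect_identical(cov$count, 17L)
    expect_equal(cov$fraction, 17 / 30)
    expect_equal(round(100 * cov$fraction, 1), 56.7)
    cnts2 <- c(rep(250, 29), 10)
    cov2 <- effectiveCoverage(cnts2, 200)
    expect_identical(cov2$count, 29L)
    expect_equal(round(100 * cov2$fraction, 1), 96.7)
    expect_identical(effectiveCoverage(cnts, 0)$count, 30L)
    expect_equal(effectiveCoverage(cnts, 0)$fraction, 1)

    expect_equal(effectiveSampleProportion(c(300, 400), 200), 1)
    expect_equal(effectiveSampleProportion(c(100, 10), 50), 100 / 110)
    # both statistics are non-increasing in n0
    set.seed(13)
    for (k in 1:10) {
        v <- sample(0:400, 15, replace = TRUE)
        if (sum(v) == 0) next
        thr <- sort(sample(0:400, 8))
        cv <- vapply(thr, function(t) effectiveCoverage(v, t)$fraction, 0)
        sp <- vapply(thr, function(t) effectiveSampleProportion(v, t), 0)
        expect_true(all(diff(cv) <= 1e-12))
        expect_true(all(diff(sp) <= 1e-12))
    }
})

test_that("center histogram follows the upper-bin edge convention and
           normalizes", {
    one <- annotationOnlyDataset(data.frame(class_id = 0L, cx = .5, cy = .5,
                                            w = .2, h = .2))
    h <- centerHistogram(one, bins = 2L)
    expect_equal(h[2, 2], 1)          # center exactly on the edge goes up
    expect_equal(sum(h), 1)
    expect_equal(sum(h > 0), 1L)
    # empty sentinel
    e <- centerHistogram(annotationOnlyDataset(.emptyAnn(), 1L), bins = 4L)
    expect_identical(dim(e), c(0L, 0L))
})

test_that("uniform centers fill the grid within the 3-sigma multinomial
           band", {
    set.seed(31)
    n <- 10000L
    ann <- data.frame(class_id = 0L, cx = runif(n, .05, .95),
                      cy = runif(n, .05, .95), w = .05, h = .05)
    # map the band back to [0,1] so cells are exactly equiprobable
    ann$cx <- (ann$cx - .05) / .9; ann$cy <- (ann$cy - .05) / .9
    ann$cx <- pmin(pmax(ann$cx, .025), .975)
    ann$cy <- pmin(pmax(ann$cy, .025), .975)
    ann$w <- .05; ann$h <- .05
    h <- centerHistogram(annotationOnlyDataset(ann), bins = 4L)
    p <- 1 / 16
    bound <- 3 * sqrt(n * p * (1 - p)) / n
    expect_true(max(abs(h - p)) <= bound)
    expect_equal(sum(h), 1, tolerance = 1e-9)
})

test_that("scale histogram agrees with independent binning", {
    set.seed(17)
    s <- runif(200, 0.05, 0.95)
    ann <- data.frame(class_id = 0L, cx = .5, cy = .5, w = s, h = s)
    ds <- annotationOnlyDataset(ann)
    got <- scaleHistogram(ds, bins = 8L)
    # brute-force oracle: bin sqrt(w h) by hand with the same convention
    oracle <- rep(0, 8)
    for (v in sqrt(s * s)) {
        b <- min(8, floor(v * 8) + 1)
        oracle[b] <- oracle[b] + 1
    }
    expect_equal(got, oracle / sum(oracle), tolerance = 1e-12)
    expect_equal(sum(got), 1)
    same <- annotationOnlyDataset(data.frame(class_id = 0L, cx = .5,
                                             cy = .5, w = .3, h = .3))
    expect_identical(sum(scaleHistogram(same, 10L) > 0), 1L)
    expect_identical(scaleHistogram(annotationOnlyDataset(.emptyAnn(), 1L)),
                     numeric())
})

test_that("report comparison computes deltas and direction flags", {
    ann1 <- data.frame(class_id = rep(0:1, c(755, 2)), cx = .5, cy = .5,
                       w = .2, h = .2)
    ann2 <- data.frame(class_id = rep(0:1, c(755, 54)), cx = .5, cy = .5,
                       w = .2, h = .2)
    b <- distributionReport(annotationOnlyDataset(ann1), n0 = 54)
    a <- distributionReport(annotationOnlyDataset(ann2), n0 = 54)
    cmp <- compareReports(b, a)
    expect_equal(cmp$deltaImbalanceRatio, 755 / 54 - 377.5)
    expect_true(cmp$irDecreased)
    expect_true(cmp$coverageIncreased)
    expect_identical(cmp$deltaEffectiveCount, 1L)
    same <- compareReports(b, b)
    expect_equal(same$deltaImbalanceRatio, 0)
    expect_equal(same$deltaLogDispersion, 0)
    expect_false(same$irDecreased)
    # mismatched class tables refuse to compare
    a2 <- a; a2@distribution@classNames <- c("x", "y")
    expect_error(compareReports(b, a2), "class tables")
})
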