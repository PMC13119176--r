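test_that("label lines parse into annotations and reject invalid input", {
    a <- parseLabelLine("0 0.5 0.5 0.2 0.1")
    expect_identical(a$class_id, 0L)
    expect_equal(unlist(a[c("cx", "cy", "w", "h")]),
                 c(cx = 0.5, cy = 0.5, w = 0.2, h = 0.1))
    expect_error(parseLabelLine("3 1.5 0.5 0.2 0.1"), "out-of-range")
    expect_error(parseLabelLine("0 0.5 0.5"), "malformed")
    expect_error(parseLabelLine("0 abc 0.5 0.2 0.1"), "non-numeric")
    expect_error(parseLabelLine("-1 0.5 0.5 0.2 0.1"), "class index")
    # box sticking out of the frame
    expect_error(parseLabelLine("0 0.05 0.5 0.2 0.1"), "out-of-range")
})

test_that("format/parse round trip preserves random valid annotations", {
    set.seed(42)
    for (k in 1:100) {
        w <- runif(1, 0.01, 1); h <- runif(1, 0.01, 1)
        ann <- data.frame(class_id = sample(0:29, 1),
                          cx = runif(1, w / 2, 1 - w / 2),
                          cy = runif(1, h / 2, 1 - h / 2), w = w, h = h)
        back <- parseLabelLine(formatLabelLine(ann))
        expect_identical(back$class_id, ann$class_id)
        expect_true(all(abs(unlist(back[2:5]) - unlist(ann[2:5])) <= 5e-7))
        # formatting is a fixed point at 6 decimals
        expect_identical(formatLabelLine(back), formatLabelLine(ann))
    }
})

test_that("write/read round trip reproduces a dataset exactly", {
    ds <- tinyDataset(nImages = 3L)
    ds@annotations[[1]] <- rbind(ds@annotations[[1]],
        data.frame(class_id = 1L, cx = 0.25, cy = 0.75, w = 0.1, h = 0.2),
        data.frame(class_id = 0L, cx = 0.8, cy = 0.2, w = 0.15, h = 0.12))
    root <- withr::local_tempdir()
    manifest <- writeDataset(ds, root)
    expect_true(file.path(root, "classes.txt") %in% manifest)
    back <- readDataset(root)
    expect_identical(nItems(back), 3L)
    expect_identical(classNames(back), classNames(ds))
    expect_identical(sum(vapply(annotations(back), nrow, 0L)), 5L)
    for (i in 1:3) {
        a0 <- annotations(ds, i); a1 <- annotations(back, i)
        expect_identical(a1$class_id, a0$class_id)
        expect_true(all(abs(as.matrix(a1[2:5]) - as.matrix(a0[2:5]))
                        <= 1e-6))
    }
    # read -> write -> read is a fixed point
    root2 <- withr::local_tempdir()
    writeDataset(back, root2)
    back2 <- readDataset(root2)
    expect_identical(lapply(annotations(back2), function(a) a[2:5]),
                     lapply(annotations(back), function(a) a[2:5]))
})

test_that("label file content uses the 6-decimal convention", {
    ds <- tinyDataset(nImages = 1L)
    ds@annotations[[1]] <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                                      w = 0.2, h = 0.1)
    root <- withr::local_tempdir()
    writeDataset(ds, root)
    lbl <- readLines(list.files(file.path(root, "labels"),
                                full.names = TRUE))
    expect_identical(lbl, "0 0.500000 0.500000 0.200000 0.100000")
})

test_that("writing an empty dataset emits nothing", {
    ds <- DetectionDataset(list(), list(), "c0")
    root <- file.path(withr::local_tempdir(), "empty_out")
    expect_identical(writeDataset(ds, root), character())
    expect_false(dir.exists(root))
})

test_that("images without label files become background items", {
    ds <- tinyDataset(nImages = 2L)
    root <- withr::local_tempdir()
    writeDataset(ds, root)
    file.remove(file.path(root, "labels", "img_002.txt"))
    expect_message(back <- readDataset(root), "background")
    expect_identical(nrow(annotations(back, 2L)), 0L)
    expect_identical(nItems(back), 2L)
})

test_that("stratified split honours ratios on single-class data", {
    imgs <- replicate(100, flatImage(8L), simplify = FALSE)
    names(imgs) <- sprintf("i%03d", 1:100)
    anns <- replicate(100, data.frame(class_id = 0L, cx = .5, cy = .5,
                                      w = .2, h = .2), simplify = FALSE)
    ds <- DetectionDataset(imgs, anns, "only")
    sp <- stratifiedSplit(ds, c(0.8, 0.1, 0.1), seed = 5L)
    expect_identical(vapply(sp, nItems, 0L),
                     c(train = 80L, val = 10L, test = 10L))
    expect_error(stratifiedSplit(ds, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("stratified split is exhaustive, disjoint, proportional per class
           and deterministic", {
    set.seed(9)
    imgs <- list(); anns <- list()
    for (cl in 0:9) for (r in 1:20) {
        i <- length(imgs) + 1L
        imgs[[sprintf("i%03d", i)]] <- flatImage(8L)
        anns[[i]] <- data.frame(class_id = cl, cx = .5, cy = .5,
                                w = .2, h = .2)
    }
    ds <- DetectionDataset(imgs, anns, sprintf("c%d", 0:9))
    sp <- stratifiedSplit(ds, seed = 3L)
    sizes <- vapply(sp, nItems, 0L)
    expect_identical(sum(sizes), 200L)
    allStems <- unname(unlist(lapply(sp, function(s) names(s@images))))
    expect_identical(sort(allStems), sort(names(ds@images)))  # no overlap/loss
    for (cl in 0:9) {
        perSplit <- vapply(sp, function(s)
            sum(vapply(annotations(s), function(a)
                sum(a$class_id == cl), 0L)), 0L)
        expect_true(all(abs(perSplit - 20 * c(.8, .1, .1)) <= 1))
        expect_true(all(perSplit > 0))  # every class in every split
    }
    sp2 <- stratifiedSplit(ds, seed = 3L)
    expect_identical(lapply(sp, function(s) names(s@images)),
                     lapply(sp2, function(s) names(s@images)))
})

test_that("multi-class images are stratified by majority class with
           low-id tie-break", {
    ann <- data.frame(class_id = c(1L, 1L, 0L), cx = c(.2, .5, .8),
                      cy = .5, w = .1, h = .1)
    tie <- data.frame(class_id = c(2L, 0L), cx = c(.3, .7), cy = .5,
                      w = .1, h = .1)
    ds <- DetectionDataset(list(a = flatImage(8L), b = flatImage(8L)),
                           list(ann, tie), c("c0", "c1", "c2"))
    # internal stratum rule is exercised through determinism of assignment:
    # majority class 1 for the first image, tie -> class 0 for the second;
    # with one image per stratum everything lands in train
    sp <- stratifiedSplit(ds, c(0.8, 0.1, 0.1), seed = 1L)
    expect_identical(nItems(sp$train), 2L)
})
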