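# Shared in-code fixtures: everything is generated at test time.

# A deterministic flat-color image with known content.
flatImage <- function(S = 32L, value = 0.5) {
    array(value, c(S, S, 3))
}

# Minimal hand-built dataset: nImages images, one box each, round-robin
# class assignment.
tinyDataset <- function(nImages = 3L, nClasses = 2L, S = 32L) {
    imgs <- list(); anns <- list()
    for (i in seq_len(nImages)) {
        img <- flatImage(S, value = i / (nImages + 1))
        imgs[[sprintf("img_%03d", i)]] <- img
        anns[[i]] <- data.frame(class_id = (i - 1L) %% nClasses,
                                cx = 0.5, cy = 0.5, w = 0.4, h = 0.3)
    }
    DetectionDataset(imgs, anns, sprintf("c%d", seq_len(nClasses) - 1L))
}

# Dataset wrapper around a bare annotation table (histograms and stats only
# look at annotations, so one dummy image suffices).
annotationOnlyDataset <- function(ann, nClasses = max(ann$class_id) + 1L) {
    DetectionDataset(list(flatImage(4L)), list(ann),
                     sprintf("c%d", seq_len(nClasses) - 1L))
}

# One-paste augmented sample on a flat background; donor is a flat patch of
# a distinct value so pixel provenance is checkable.
onePasteSample <- function(S = 32L, donorValue = 0.9, blendMode = "hard") {
    bg <- asAugmentedSample(flatImage(S, 0.2), .emptyAnn())
    donor <- new("LesionInstance",
                 pixels = array(donorValue, c(8, 8, 3)),
                 alpha = matrix(1, 8, 8), classId = 0L,
                 source = list(item = "donor", annIndex = 1L),
                 nativeScale = 8 / S)
    pasteInstance(bg, donor, c(0.5, 0.5), 1, blendMode)
}

.emptyAnn <- function() {
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
}

# Frozen small fixture spec reused across module tests.
smallFixtureSpec <- function(seed = 11L, counts = c(20L, 10L, 6L, 3L, 2L),
                             S = 64L) {
    fixtureSpec(classCounts = counts, imageSize = S, seed = seed,
                scaleRange = c(0.1, 0.3))
}
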