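#' FixtureSpec: recipe for a procedural leaf/lesion dataset
#'
#' Describes a synthetic detection dataset emulating the statistical
#' structure of field-photographed plant-disease collections: a long-tailed
#' per-class count vector, a center-biased placement law, and a narrow
#' normalized-scale band. Images are procedurally drawn leaves (textured
#' ellipse on soil-toned noise) carrying per-class parameterized lesion
#' blobs; classes are visually separable by color/texture so an oracle
#' teacher can be meaningful, without attempting photorealism.
#'
#' @slot classCounts integer vector of requested instances per class.
#' @slot imageSize integer pixel side of the square frames.
#' @slot centerBias numeric in [0, 1]; 0 = uniform placement, 1 = tight
#'   central Gaussian (the mixture weight of the truncated Gaussian
#'   component).
#' @slot scaleRange numeric(2); normalized \eqn{\sqrt{wh}} bounds in (0, 1].
#' @slot maxPerImage integer; lesions drawn per frame at most.
#' @slot styles per-class appearance: list of lists (color, eccentricity,
#'   speckle).
#' @slot seed integer; generation is a pure function of the spec.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
    representation(classCounts = "integer", imageSize = "integer",
                   centerBias = "numeric", scaleRange = "numeric",
                   maxPerImage = "integer", styles = "list",
                   seed = "integer"))

setValidity("FixtureSpec", function(object) {
    if (any(object@classCounts < 0L))
        return("class counts must be non-negative")
    if (object@centerBias < 0 || object@centerBias > 1)
        return("centerBias must lie in [0, 1]")
    sr <- object@scaleRange
    if (length(sr) != 2L || sr[1] <= 0 || sr[2] > 1 || sr[1] > sr[2])
        return("scaleRange must be (min, max) within (0, 1]")
    if (length(object@styles) != length(object@classCounts))
        return("one style per class required")
    TRUE
})

#' @param numClasses number of classes (default 30).
#' @param classCounts explicit per-class instance counts; if \code{NULL}, a
#'   geometric decay from \code{headCount} down to \code{tailCount} over
#'   \code{numClasses} classes is used (endpoints exact).
#' @param headCount,tailCount extremes of the default long tail; the
#'   defaults 755 and 2 reproduce the pre-augmentation imbalance ratio
#'   of 377.5 characteristic of field plant-disease data.
#' @param imageSize square frame side in pixels.
#' @param centerBias mixture weight of the central truncated Gaussian in the
#'   placement law.
#' @param scaleRange normalized \eqn{\sqrt{wh}} range of drawn lesions.
#' @param maxPerImage at most this many lesions per frame.
#' @param seed integer seed; fixes both the style table and image content.
#' @return a \linkS4class{FixtureSpec}.
#' @rdname FixtureSpec-class
#' @examples
#' spec <- fixtureSpec(numClasses = 4, headCount = 20, tailCount = 2,
#'                     imageSize = 64, seed = 7)
#' sum(spec@classCounts)
#' @export
fixtureSpec <- function(numClasses = 30L, classCounts = NULL,
                        headCount = 755L, tailCount = 2L,
                        imageSize = 256L, centerBias = 0.6,
                        scaleRange = c(0.06, 0.22), maxPerImage = 3L,
                        seed = 1L) {
    if (is.null(classCounts)) {
        k <- numClasses
        if (k == 1L) {
            classCounts <- headCount
        } else {
            r <- (tailCount / headCount)^(1 / (k - 1))
            classCounts <- round(headCount * r^(seq_len(k) - 1))
            classCounts[1] <- headCount
            classCounts[k] <- tailCount
        }
    }
    k <- length(classCounts)
    set.seed(.stageSeed(seed, "fixture_styles"))
    hue <- ((seq_len(k) - 1) * 0.61803398875 + 0.03) %% 1
    styles <- lapply(seq_len(k), function(i) {
        list(color = as.vector(grDevices::col2rgb(
                 grDevices::hsv(hue[i], runif(1, 0.55, 0.95),
                                runif(1, 0.45, 0.9))) / 255),
             eccentricity = runif(1, 0.45, 0.95),
             speckle = runif(1, 0.02, 0.12))
    })
    new("FixtureSpec", classCounts = as.integer(classCounts),
        imageSize = as.integer(imageSize), centerBias = centerBias,
        scaleRange = as.numeric(scaleRange),
        maxPerImage = as.integer(maxPerImage), styles = styles,
        seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf(paste0("FixtureSpec: %d classes, %d instances ",
                       "(min %d, max %d), %dpx frames\n"),
                length(object@classCounts), sum(object@classCounts),
                min(object@classCounts), max(object@classCounts),
                object@imageSize))
})

# Draw a center from (1 - b) * Uniform(band) + b * truncated N(0.5, 0.12^2).
.drawCenter <- function(halfW, halfH, bias) {
    band <- function(half) c(half, 1 - half)
    one <- function(half) {
        b <- band(half)
        if (b[1] >= b[2]) return(0.5)
        if (runif(1) >= bias) return(runif(1, b[1], b[2]))
        repeat {
            v <- rnorm(1, 0.5, 0.12)
            if (v >= b[1] && v <= b[2]) return(v)
        }
    }
    c(cx = one(halfW), cy = one(halfH))
}

.boxIoUXYWH <- function(a, b) {
    ax0 <- a[1] - a[3] / 2; ax1 <- a[1] + a[3] / 2
    ay0 <- a[2] - a[4] / 2; ay1 <- a[2] + a[4] / 2
    bx0 <- b[1] - b[3] / 2; bx1 <- b[1] + b[3] / 2
    by0 <- b[2] - b[4] / 2; by1 <- b[2] + b[4] / 2
    iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
    ih <- max(0, min(ay1, by1) - max(ay0, by0))
    inter <- iw * ih
    un <- a[3] * a[4] + b[3] * b[4] - inter
    if (un <= 0) 0 else inter / un
}

# Soil-noise background with a textured leaf ellipse.
.drawLeafBackground <- function(S) {
    soil <- c(0.33, 0.25, 0.17)
    n <- matrix(runif(S * S, -0.06, 0.06), S, S)
    img <- array(0, c(S, S, 3))
    for (ch in 1:3)
        img[, , ch] <- soil[ch] + n + runif(1, -0.02, 0.02)
    rc <- S * runif(1, 0.45, 0.55); cc <- S * runif(1, 0.45, 0.55)
    ra <- S * runif(1, 0.38, 0.46); ca <- S * runif(1, 0.38, 0.46)
    theta <- runif(1, 0, pi)
    leaf <- .ellipseMask(S, S, rc, cc, ra, ca, theta)
    # coarse mottling upsampled to frame size + vein-like periodic darkening
    coarse <- .resizeMatrix(matrix(runif(64, -0.05, 0.05), 8, 8), S, S)
    rows <- matrix(seq_len(S), S, S); cols <- matrix(seq_len(S), S, S,
                                                     byrow = TRUE)
    ax <- (rows - rc) * sin(theta) + (cols - cc) * cos(theta)
    vein <- 0.06 * (abs(sin(ax * 14 / S * pi)) < 0.12)
    green <- c(0.21, 0.46, 0.15)
    for (ch in 1:3) {
        plane <- img[, , ch]
        plane[leaf] <- (green[ch] + coarse[leaf] - vein[leaf])
        img[, , ch] <- plane
    }
    pmin(pmax(img, 0), 1)
}

# Draw one lesion blob; returns its soft mask extent and the annotation box
# derived from the mask so boxes and masks agree by construction.
.drawLesion <- function(img, style, cx, cy, wn, hn) {
    S <- dim(img)[1]
    rc <- cy * S; cc <- cx * S
    ra <- hn * S / 2; ca <- wn * S / 2
    px <- .boxToPixels(cx, cy, wn, hn, S, S)
    rows <- px$rows; cols <- px$cols
    r <- matrix(rows, length(rows), length(cols)) - rc
    c <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cc
    d2 <- (r / ra)^2 + (c / ca)^2
    alpha <- pmax(1 - d2, 0)^0.5
    col <- style$color
    spek <- matrix(runif(length(alpha), -style$speckle, style$speckle),
                   nrow(alpha))
    for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        les <- pmin(pmax(col[ch] + spek, 0), 1)
        img[rows, cols, ch] <- plane * (1 - alpha) + les * alpha
    }
    keepR <- which(apply(alpha > 0, 1, any))
    keepC <- which(apply(alpha > 0, 2, any))
    rows <- rows[keepR]; cols <- cols[keepC]
    alpha <- alpha[keepR, keepC, drop = FALSE]
    list(img = img, box = .pixelsToBox(rows, cols, S, S),
         mask = list(rows = rows, cols = cols, alpha = alpha))
}

#' Generate a synthetic leaf/lesion detection dataset
#'
#' Realizes a \linkS4class{FixtureSpec} exactly: the per-class instance
#' counts of the output equal the requested vector, lesion centers follow
#' the center-bias mixture law, scales are uniform on the requested
#' \eqn{\sqrt{wh}} range, and ground-truth boxes within one frame overlap at
#' IoU of at most 0.1 so a teacher's box matching stays unambiguous. Every
#' drawn lesion carries a soft mask whose support rectangle equals its
#' annotation box (to the pixel grid). Generation is a pure function of the
#' spec, seed included.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param outDir if non-\code{NULL}, write the dataset in YOLO layout there
#'   and keep only file references in memory (recommended for large specs).
#' @param keepMasks retain per-object soft masks in the returned object.
#' @return a \linkS4class{DetectionDataset}.
#' @examples
#' ds <- generateDataset(fixtureSpec(numClasses = 3, classCounts = c(4, 2, 1),
#'                                   imageSize = 48, seed = 3))
#' counts(classDistribution(ds))
#' @export
generateDataset <- function(spec, outDir = NULL, keepMasks = is.null(outDir)) {
    stopifnot(is(spec, "FixtureSpec"))
    S <- spec@imageSize
    kcls <- length(spec@classCounts)
    clsNames <- sprintf("lesion_%02d", seq_len(kcls) - 1L)
    set.seed(.stageSeed(spec@seed, "fixture_images"))
    pool <- rep(seq_len(kcls) - 1L, spec@classCounts)
    pool <- pool[sample.int(length(pool))]
    # feasibility: the largest box must fit the frame
    if (spec@scaleRange[2] > 1)
        stop("scaleRange exceeds the frame; use larger images")
    if (!is.null(outDir)) {
        dir.create(file.path(outDir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
        dir.create(file.path(outDir, "labels"), recursive = TRUE,
                   showWarnings = FALSE)
    }
    images <- list(); anns <- list(); masks <- list()
    idx <- 0L
    while (length(pool) > 0L) {
        idx <- idx + 1L
        nHere <- min(length(pool), sample.int(spec@maxPerImage, 1L))
        img <- .drawLeafBackground(S)
        ann <- .emptyAnnotations()
        mk <- list()
        placedBoxes <- list()
        placed <- 0L
        while (placed < nHere && length(pool) > 0L) {
            cid <- pool[1]
            sty <- spec@styles[[cid + 1L]]
            s <- runif(1, spec@scaleRange[1], spec@scaleRange[2])
            ar <- sqrt(1 / sty$eccentricity)
            wn <- min(0.98, s * ar); hn <- min(0.98, s / ar)
            ok <- FALSE
            for (try in 1:60) {
                ctr <- .drawCenter(wn / 2, hn / 2, spec@centerBias)
                cand <- c(ctr["cx"], ctr["cy"], wn, hn)
                ious <- vapply(placedBoxes,
                               function(b) .boxIoUXYWH(cand, b), 0)
                if (all(ious <= 0.1)) { ok <- TRUE; break }
            }
            if (!ok) break  # frame too crowded; start a new image
            les <- .drawLesion(img, sty, cand[1], cand[2], wn, hn)
            img <- les$img
            b <- les$box
            ann <- rbind(ann, data.frame(class_id = cid, cx = b$cx,
                                         cy = b$cy, w = b$w, h = b$h))
            placedBoxes[[length(placedBoxes) + 1L]] <- cand
            mk[[length(mk) + 1L]] <- les$mask
            pool <- pool[-1]
            placed <- placed + 1L
        }
        stem <- sprintf("fix_%05d", idx)
        if (!is.null(outDir)) {
            ip <- file.path(outDir, "images", paste0(stem, ".png"))
            writeImageFile(img, ip)
            writeLines(vapply(seq_len(nrow(ann)), function(j)
                formatLabelLine(ann[j, ]), ""),
                file.path(outDir, "labels", paste0(stem, ".txt")))
            images[[stem]] <- ip
        } else {
            images[[stem]] <- img
        }
        anns[[idx]] <- ann
        if (keepMasks) masks[[idx]] <- mk
    }
    if (!is.null(outDir))
        writeLines(clsNames, file.path(outDir, "classes.txt"))
    DetectionDataset(images, anns, clsNames,
                     masks = if (keepMasks) masks else list())
}

#' Construct an oracle teacher
#'
#' A ground-truth-aware detector double for exercising the accept-reject
#' screen: see \linkS4class{OracleTeacher} for the behavioural law. The
#' adversarial variant is \code{oracleTeacher(detectionProb = 0)}, which
#' never detects anything.
#'
#' @param detectionProb per-box detection probability.
#' @param confBase,confSd confidence law: reported confidence is
#'   \code{N(confBase, confSd)} truncated to [0, 1].
#' @param locNoise Gaussian jitter (in pixels) added to detected box corners.
#' @return an \linkS4class{OracleTeacher}.
#' @examples
#' perfect <- oracleTeacher()
#' noisy <- oracleTeacher(detectionProb = 0.7, confBase = 0.8, confSd = 0.1)
#' @export
oracleTeacher <- function(detectionProb = 1, confBase = 1, confSd = 0,
                          locNoise = 0) {
    new("OracleTeacher", detectionProb = detectionProb, confBase = confBase,
        confSd = confSd, locNoise = locNoise)
}
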