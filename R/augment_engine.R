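#' AugPolicy: category-aware copy-paste policy
#'
#' Controls the augmentation planner. Augmentation is deficit-to-target:
#' every class below its target count \eqn{T_i} receives
#' \eqn{\max(0, T_i - N_i)} pasted instances (a floor scheme, matching the
#' post-augmentation per-class floors such schemes produce directly);
#' classes at or above target are left untouched, so class counts never
#' decrease and, with tail-only targets, the imbalance ratio cannot
#' increase.
#'
#' @slot targetCount numeric; scalar floor applied to every class, or a
#'   per-class vector.
#' @slot scaleJitter numeric(2); multiplicative range applied to a donor's
#'   native scale, clipped so the scaled box stays inside the unit frame.
#' @slot maxPastePerImage integer; pastes per synthesized image at most.
#' @slot maxOverlapIoU numeric in [0, 1); tolerated IoU between a pasted box
#'   and any existing box.
#' @slot blendMode "feathered" or "hard".
#' @slot retryBudget integer; placement rejection-sampling attempts.
#' @slot onReject "drop" or "resample": what the pipeline does with samples
#'   the teacher screen rejects.
#' @exportClass AugPolicy
setClass("AugPolicy",
    representation(targetCount = "numeric", scaleJitter = "numeric",
                   maxPastePerImage = "integer", maxOverlapIoU = "numeric",
                   blendMode = "character", retryBudget = "integer",
                   onReject = "character"))

setValidity("AugPolicy", function(object) {
    if (any(object@targetCount < 0))
        return("targetCount must be non-negative")
    if (object@scaleJitter[1] <= 0 ||
        object@scaleJitter[1] > object@scaleJitter[2])
        return("scaleJitter must be an increasing positive range")
    if (object@maxOverlapIoU < 0 || object@maxOverlapIoU >= 1)
        return("maxOverlapIoU must lie in [0, 1)")
    if (!object@blendMode %in% c("feathered", "hard"))
        return("blendMode must be 'feathered' or 'hard'")
    if (!object@onReject %in% c("drop", "resample"))
        return("onReject must be 'drop' or 'resample'")
    TRUE
})

#' @param targetCount per-class post-augmentation floor (scalar or vector).
#' @param scaleJitter multiplicative scale range (default 0.5-2.0).
#' @param maxPastePerImage pastes per synthesized image at most.
#' @param maxOverlapIoU tolerated IoU with existing boxes (default 0.1).
#' @param blendMode "feathered" (cosine-soft border) or "hard".
#' @param retryBudget placement attempts per paste (default 50).
#' @param onReject "drop" or "resample".
#' @return an \linkS4class{AugPolicy}.
#' @rdname AugPolicy-class
#' @export
augPolicy <- function(targetCount, scaleJitter = c(0.5, 2),
                      maxPastePerImage = 3L, maxOverlapIoU = 0.1,
                      blendMode = c("feathered", "hard"),
                      retryBudget = 50L, onReject = c("drop", "resample")) {
    new("AugPolicy", targetCount = as.numeric(targetCount),
        scaleJitter = as.numeric(scaleJitter),
        maxPastePerImage = as.integer(maxPastePerImage),
        maxOverlapIoU = maxOverlapIoU, blendMode = match.arg(blendMode),
        retryBudget = as.integer(retryBudget),
        onReject = match.arg(onReject))
}

#' Per-class paste deficits
#'
#' \eqn{deficit_i = \max(0, T_i - N_i)}: how many instances each class needs
#' to reach its target floor. Classes already at or above target get 0.
#'
#' @param d a \linkS4class{ClassDistribution} or count vector.
#' @param target scalar or per-class target vector \eqn{T}.
#' @return named integer vector of deficits.
#' @examples
#' classDeficits(c(755, 2), 54)   # 0, 52
#' @export
classDeficits <- function(d, target) {
    cnt <- if (is(d, "ClassDistribution")) counts(d) else
        setNames(as.numeric(d), names(d))
    stopifnot(all(target > 0))
    if (length(target) == 1L)
        target <- rep(target, length(cnt))
    if (length(target) != length(cnt))
        stop("target must be a scalar or one value per class")
    def <- pmax(0, ceiling(target) - cnt)
    storage.mode(def) <- "integer"
    def
}

#' Wrap an image and its annotations as an unaugmented sample
#'
#' @param img numeric \code{H x W x 3} array.
#' @param ann annotation data.frame.
#' @return an \linkS4class{AugmentedSample} with empty provenance.
#' @export
asAugmentedSample <- function(img, ann) {
    new("AugmentedSample", image = .asRaster(img), annotations = ann,
        provenance = data.frame(annIndex = integer(), donorItem = character(),
                                donorAnnIndex = integer(), classId = integer(),
                                cx = numeric(), cy = numeric(),
                                scaleFactor = numeric(),
                                blendMode = character(), effects = character()),
        visibleFraction = rep(1, nrow(ann)), pendingScreen = TRUE)
}

#' Sample a paste placement
#'
#' Draws a box center uniformly over the positions that keep the whole box
#' inside the frame, rejecting positions whose IoU with any existing box
#' exceeds \code{maxOverlapIoU}. This uniform law deliberately covers
#' corners and edge regions that center-biased field photography leaves
#' empty. Returns \code{NULL} when the retry budget is exhausted (the
#' caller skips the paste).
#'
#' @param boxSize numeric(2): normalized (w, h) of the box to place.
#' @param existing annotation data.frame of boxes already in the frame.
#' @param maxOverlapIoU tolerated IoU.
#' @param retryBudget attempts.
#' @return numeric(2) center \code{(cx, cy)}, or \code{NULL}.
#' @export
samplePlacement <- function(boxSize, existing = NULL, maxOverlapIoU = 0.1,
                            retryBudget = 50L) {
    wn <- boxSize[1]; hn <- boxSize[2]
    if (wn > 1 || hn > 1)
        stop("box does not fit in the frame")
    lo <- c(wn / 2, hn / 2); hi <- c(1 - wn / 2, 1 - hn / 2)
    nEx <- if (is.null(existing)) 0L else nrow(existing)
    for (try in seq_len(retryBudget)) {
        cx <- if (lo[1] >= hi[1]) 0.5 else runif(1, lo[1], hi[1])
        cy <- if (lo[2] >= hi[2]) 0.5 else runif(1, lo[2], hi[2])
        ok <- TRUE
        if (nEx > 0L) {
            for (j in seq_len(nEx)) {
                iou <- .boxIoUXYWH(c(cx, cy, wn, hn),
                                   c(existing$cx[j], existing$cy[j],
                                     existing$w[j], existing$h[j]))
                if (iou > maxOverlapIoU) { ok <- FALSE; break }
            }
        }
        if (ok)
            return(c(cx = cx, cy = cy))
    }
    NULL
}

#' Paste a donor instance into a sample
#'
#' Rescales the donor crop (bilinear) so its normalized \eqn{\sqrt{wh}} in
#' the target frame equals \code{scaleFactor} times the donor's native
#' scale, alpha-composites it at \code{center}, and appends the new
#' annotation. In \code{"hard"} mode the alpha mask is binarized, so pixels
#' outside the pasted rectangle are bit-identical to the background; in
#' \code{"feathered"} mode the crop's soft mask is used and the recorded box
#' is the extent of alpha > 0.5. Original annotations are never modified.
#'
#' @param sample an \linkS4class{AugmentedSample} (the background).
#' @param instance a \linkS4class{LesionInstance}.
#' @param center numeric(2) normalized \code{(cx, cy)}.
#' @param scaleFactor multiplicative factor on the donor's native scale.
#' @param blendMode "feathered" or "hard".
#' @return the sample with one more annotation and provenance row.
#' @export
pasteInstance <- function(sample, instance, center, scaleFactor = 1,
                          blendMode = c("feathered", "hard")) {
    blendMode <- match.arg(blendMode)
    stopifnot(is(sample, "AugmentedSample"), is(instance, "LesionInstance"))
    img <- sample@image
    H <- dim(img)[1]; W <- dim(img)[2]
    crop <- instance@pixels
    alpha <- instance@alpha
    hc <- dim(crop)[1]; wc <- dim(crop)[2]
    # linear resize factor taking the crop's normalized sqrt-area in the
    # target frame to scaleFactor * nativeScale
    cur <- sqrt((hc / H) * (wc / W))
    f <- scaleFactor * instance@nativeScale / cur
    ht <- max(2L, round(hc * f)); wt <- max(2L, round(wc * f))
    if (ht > H || wt > W)
        stop("scaled crop exceeds the frame")
    if (blendMode == "hard")
        alpha <- matrix(1, nrow(alpha), ncol(alpha))
    crop <- .resizeRaster(crop, ht, wt)
    alpha <- .resizeMatrix(alpha, ht, wt)
    if (blendMode == "hard")
        alpha[] <- 1
    r0 <- round(center[2] * H - ht / 2)
    c0 <- round(center[1] * W - wt / 2)
    if (r0 < 0 || c0 < 0 || r0 + ht > H || c0 + wt > W)
        stop("crop out of frame at this center; re-place")
    rows <- (r0 + 1L):(r0 + ht); cols <- (c0 + 1L):(c0 + wt)
    for (ch in 1:3)
        img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) +
            crop[, , ch] * alpha
    # recorded box: extent of alpha > 0.5 (hard mode: the full rectangle)
    core <- alpha > 0.5
    kr <- which(apply(core, 1, any)); kc <- which(apply(core, 2, any))
    if (!length(kr)) { kr <- seq_len(ht); kc <- seq_len(wt) }
    b <- .pixelsToBox(rows[kr], cols[kc], H, W)
    newAnn <- data.frame(class_id = instance@classId, cx = b$cx, cy = b$cy,
                         w = b$w, h = b$h)
    sample@image <- img
    sample@annotations <- rbind(sample@annotations, newAnn)
    ai <- nrow(sample@annotations)
    srcItem <- if (is.character(instance@source$item))
        instance@source$item else as.character(instance@source$item)
    sample@provenance <- rbind(sample@provenance,
        data.frame(annIndex = ai, donorItem = srcItem,
                   donorAnnIndex = instance@source$annIndex,
                   classId = instance@classId, cx = b$cx, cy = b$cy,
                   scaleFactor = scaleFactor, blendMode = blendMode,
                   effects = ""))
    sample@visibleFraction <- c(sample@visibleFraction, 1)
    sample
}

# Clip the jittered scale so the scaled crop fits the frame with margin.
.clipScaleFactor <- function(f, instance, H, W) {
    hc <- dim(instance@pixels)[1]; wc <- dim(instance@pixels)[2]
    cur <- sqrt((hc / H) * (wc / W))
    lin <- f * instance@nativeScale / cur
    linMax <- 0.95 * min(H / hc, W / wc)
    linMin <- 2.5 / min(hc, wc)
    lin <- min(max(lin, linMin), linMax)
    lin * cur / instance@nativeScale
}

#' Plan and execute category-aware copy-paste augmentation
#'
#' For every deficit class (processed in descending deficit order) the
#' planner synthesizes images until \eqn{N_i + pastes_i \ge T_i}: a
#' background is drawn uniformly from the whole dataset (any class, so rare
#' lesions appear in diverse contexts), donors are sampled with replacement
#' from the bank, scales are jittered, placements drawn uniformly over the
#' frame with bounded-overlap rejection, and the environment stage is
#' applied per profile. Each emitted \linkS4class{AugmentedSample} carries
#' full provenance. Deterministic given \code{seed}.
#'
#' When a \code{teacher} is supplied, each sample is screened immediately;
#' with \code{policy@onReject == "resample"} a rejected sample is re-drawn
#' (fresh background/placement/effects) up to \code{maxResample} times.
#'
#' @param ds background/source \linkS4class{DetectionDataset}.
#' @param bank a \linkS4class{LesionBank} with donors for every deficit
#'   class (otherwise an error lists the missing classes).
#' @param policy an \linkS4class{AugPolicy}.
#' @param profile an \linkS4class{EnvProfile} or \code{NULL}.
#' @param teacher optional \linkS4class{TeacherModel} for inline screening.
#' @param screenCfg a \linkS4class{ScreeningConfig} (used when
#'   \code{teacher} is given).
#' @param seed integer seed.
#' @param sink optional \code{function(sample, screen)} called per emitted
#'   sample (for streaming pipelines); when supplied, samples are not
#'   accumulated in memory.
#' @param maxResample resample attempts per rejected sample.
#' @return list with \code{samples} (list, empty when \code{sink} given),
#'   \code{screens} (list of \linkS4class{ScreeningResult} or NULL),
#'   \code{planned} (the planned post-augmentation
#'   \linkS4class{ClassDistribution}), \code{pastes} (named per-class paste
#'   counts) and \code{failures} (pastes abandoned for lack of space).
#' @export
planAndAugment <- function(ds, bank, policy, profile = NULL, teacher = NULL,
                           screenCfg = NULL, seed = 1L, sink = NULL,
                           maxResample = 3L) {
    stopifnot(is(ds, "DetectionDataset"), is(bank, "LesionBank"),
              is(policy, "AugPolicy"))
    d <- classDistribution(ds)
    def <- classDeficits(d, policy@targetCount)
    avail <- bankCounts(bank)
    missing <- which(def > 0L & avail == 0L)
    if (length(missing))
        stop("deficit class(es) with no donor instances: ",
             paste(d@classNames[missing], collapse = ", "))
    if (!is.null(teacher) && is.null(screenCfg))
        screenCfg <- screeningConfig()
    set.seed(.stageSeed(seed, "augment"))
    order_ <- order(def, decreasing = TRUE)
    pastes <- setNames(integer(length(def)), d@classNames)
    failures <- 0L
    samples <- list(); screens <- list()
    makeSample <- function(cid0, nPaste) {
        bi <- sample.int(nItems(ds), 1L)
        smp <- asAugmentedSample(getImage(ds, bi), ds@annotations[[bi]])
        attr(smp, "backgroundItem") <- bi
        done <- 0L
        for (p in seq_len(nPaste)) {
            inst <- sampleInstance(bank, cid0)
            sf <- runif(1, policy@scaleJitter[1], policy@scaleJitter[2])
            sf <- .clipScaleFactor(sf, inst, dim(smp@image)[1],
                                   dim(smp@image)[2])
            hc <- dim(inst@pixels)[1]; wc <- dim(inst@pixels)[2]
            H <- dim(smp@image)[1]; W <- dim(smp@image)[2]
            lin <- sf * inst@nativeScale / sqrt((hc / H) * (wc / W))
            bs <- c(min(1, round(wc * lin) / W), min(1, round(hc * lin) / H))
            ctr <- samplePlacement(bs, smp@annotations, policy@maxOverlapIoU,
                                   policy@retryBudget)
            if (is.null(ctr))
                next
            smp <- pasteInstance(smp, inst, ctr, sf, policy@blendMode)
            done <- done + 1L
        }
        list(sample = applyEnvironment(smp, profile), done = done)
    }
    for (ci in order_) {
        remaining <- def[ci]
        cid0 <- ci - 1L
        stall <- 0L
        while (remaining > 0L) {
            nPaste <- min(remaining, sample.int(policy@maxPastePerImage, 1L))
            res <- makeSample(cid0, nPaste)
            if (res$done == 0L) {
                stall <- stall + 1L
                if (stall >= 20L) {
                    warning("placement budget exhausted for class ",
                            d@classNames[ci], "; ", remaining,
                            " paste(s) unplanned", call. = FALSE)
                    failures <- failures + remaining
                    break
                }
                next
            }
            stall <- 0L
            scr <- NULL
            smp <- res$sample
            if (!is.null(teacher)) {
                scr <- screenSample(smp, teacher, screenCfg)
                if (!scr@accepted && policy@onReject == "resample") {
                    for (k in seq_len(maxResample)) {
                        res2 <- makeSample(cid0, nPaste)
                        if (res2$done == 0L) next
                        scr2 <- screenSample(res2$sample, teacher, screenCfg)
                        if (scr2@accepted) {
                            smp <- res2$sample; scr <- scr2
                            res$done <- res2$done
                            break
                        }
                    }
                }
                smp@pendingScreen <- FALSE
            }
            pastes[ci] <- pastes[ci] + res$done
            remaining <- remaining - res$done
            if (is.null(sink)) {
                samples[[length(samples) + 1L]] <- smp
                screens <- c(screens, list(scr))
            } else {
                sink(smp, scr)
            }
        }
    }
    planned <- classDistribution(d@counts + as.integer(pastes), d@classNames)
    list(samples = samples, screens = screens, planned = planned,
         pastes = pastes, failures = failures)
}
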