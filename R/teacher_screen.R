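#' ScreeningConfig: accept-reject thresholds
#'
#' The teacher screen accepts a pasted box when its best-matching teacher
#' detection has IoU at least \code{iouMin} (localization consistency),
#' confidence at least \code{confMin}, the predicted class matches (when
#' required), and the box's visible fraction after occlusion is at least
#' \code{minVisibleFraction}. The defaults (confMin 0.25, iouMin 0.5,
#' class match required, visibility 0.5) are deliberate configuration, not
#' derived constants; all four are mandatory fields of the screen.
#'
#' @slot confMin numeric in [0, 1]; confidence threshold tau.
#' @slot iouMin numeric in [0, 1]; localization threshold theta.
#' @slot requireClassMatch logical.
#' @slot minVisibleFraction numeric in [0, 1].
#' @exportClass ScreeningConfig
setClass("ScreeningConfig",
    representation(confMin = "numeric", iouMin = "numeric",
                   requireClassMatch = "logical",
                   minVisibleFraction = "numeric"))

setValidity("ScreeningConfig", function(object) {
    for (v in c(object@confMin, object@iouMin, object@minVisibleFraction))
        if (v < 0 || v > 1)
            return("thresholds must lie in [0, 1]")
    TRUE
})

#' @param confMin,iouMin,requireClassMatch,minVisibleFraction see slots.
#' @return a \linkS4class{ScreeningConfig}.
#' @rdname ScreeningConfig-class
#' @export
screeningConfig <- function(confMin = 0.25, iouMin = 0.5,
                            requireClassMatch = TRUE,
                            minVisibleFraction = 0.5) {
    new("ScreeningConfig", confMin = confMin, iouMin = iouMin,
        requireClassMatch = requireClassMatch,
        minVisibleFraction = minVisibleFraction)
}

#' Intersection over union of two normalized boxes
#'
#' Boxes are \code{(cx, cy, w, h)} in normalized center format. Degenerate
#' zero-area boxes yield 0 by convention.
#'
#' @param a,b numeric(4) or one-row annotation data.frames.
#' @return numeric in [0, 1]; symmetric in its arguments.
#' @examples
#' boxIoU(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2))  # 1
#' @export
boxIoU <- function(a, b) {
    vec <- function(x) if (is.data.frame(x))
        c(x$cx, x$cy, x$w, x$h) else as.numeric(x)
    a <- vec(a); b <- vec(b)
    if (a[3] * a[4] <= 0 || b[3] * b[4] <= 0)
        return(0)
    .boxIoUXYWH(a, b)
}

#' @describeIn predictBoxes oracle teacher: detects each ground-truth box
#'   independently with its detection probability, jitters corners by
#'   Gaussian pixel noise, and reports truncated-Gaussian confidence.
setMethod("predictBoxes", "OracleTeacher", function(teacher, image, truth) {
    det <- .emptyAnnotations()
    det$confidence <- numeric()
    if (is.null(truth) || nrow(truth) == 0L)
        return(det)
    H <- dim(image)[1]; W <- dim(image)[2]
    for (j in seq_len(nrow(truth))) {
        if (runif(1) > teacher@detectionProb)
            next
        a <- truth[j, ]
        if (teacher@locNoise > 0) {
            jx <- rnorm(2, 0, teacher@locNoise / W)
            jy <- rnorm(2, 0, teacher@locNoise / H)
            x0 <- a$cx - a$w / 2 + jx[1]; x1 <- a$cx + a$w / 2 + jx[2]
            y0 <- a$cy - a$h / 2 + jy[1]; y1 <- a$cy + a$h / 2 + jy[2]
            x0 <- min(max(x0, 0), 1); x1 <- min(max(x1, x0 + 1e-4), 1)
            y0 <- min(max(y0, 0), 1); y1 <- min(max(y1, y0 + 1e-4), 1)
            a$cx <- (x0 + x1) / 2; a$w <- x1 - x0
            a$cy <- (y0 + y1) / 2; a$h <- y1 - y0
        }
        conf <- if (teacher@confSd > 0)
            min(max(rnorm(1, teacher@confBase, teacher@confSd), 0), 1)
        else teacher@confBase
        det <- rbind(det, data.frame(class_id = a$class_id, cx = a$cx,
                                     cy = a$cy, w = a$w, h = a$h,
                                     confidence = conf))
    }
    det
})

#' @describeIn predictBoxes function adapter: delegates to the wrapped
#'   \code{fn(image, truth)}.
setMethod("predictBoxes", "FunctionTeacher", function(teacher, image, truth) {
    teacher@fn(image, truth)
})

#' @param fn function(image, truth) returning a detection data.frame.
#' @return \code{functionTeacher}: a \linkS4class{FunctionTeacher}.
#' @rdname predictBoxes
#' @export
functionTeacher <- function(fn) new("FunctionTeacher", fn = fn)

# One-to-one greedy matching by descending IoU between pasted boxes and
# teacher detections. Returns per-pasted-box (detection index or NA, iou).
.greedyMatch <- function(pasted, det) {
    np <- nrow(pasted); nd <- nrow(det)
    match <- rep(NA_integer_, np)
    iou <- numeric(np)
    if (np == 0L || nd == 0L)
        return(list(match = match, iou = iou))
    M <- matrix(0, np, nd)
    for (i in seq_len(np))
        for (j in seq_len(nd))
            M[i, j] <- boxIoU(pasted[i, ], det[j, ])
    repeat {
        best <- which.max(M)
        if (M[best] <= 0)
            break
        i <- (best - 1L) %% np + 1L
        j <- (best - 1L) %/% np + 1L
        match[i] <- j
        iou[i] <- M[i, j]
        M[i, ] <- -1; M[, j] <- -1
        if (all(M < 0))
            break
    }
    list(match = match, iou = iou)
}

#' Screen one augmented sample with a teacher
#'
#' Realizes the accept-reject step: the teacher predicts on the final
#' (environment-perturbed) image; each pasted box is matched one-to-one to
#' the highest-IoU detection; a box passes when it is sufficiently visible,
#' well localized (IoU >= iouMin), confidently detected (>= confMin) and,
#' if required, of the right class. Verdict reasons are checked in that
#' order. Original (non-pasted) boxes are never screened. The sample is
#' accepted iff every pasted box passes; screening never mutates the image
#' or the annotations.
#'
#' @param sample an \linkS4class{AugmentedSample} with at least one pasted
#'   box.
#' @param teacher a \linkS4class{TeacherModel}.
#' @param cfg a \linkS4class{ScreeningConfig}.
#' @return a \linkS4class{ScreeningResult}.
#' @export
screenSample <- function(sample, teacher, cfg = screeningConfig()) {
    stopifnot(is(sample, "AugmentedSample"), is(teacher, "TeacherModel"))
    prov <- sample@provenance
    if (nrow(prov) == 0L)
        stop("sample has no pasted boxes to screen")
    det <- predictBoxes(teacher, sample@image, sample@annotations)
    pasted <- sample@annotations[prov$annIndex, , drop = FALSE]
    mm <- .greedyMatch(pasted, det)
    reasons <- character(nrow(pasted))
    confs <- rep(NA_real_, nrow(pasted))
    for (i in seq_len(nrow(pasted))) {
        vis <- sample@visibleFraction[prov$annIndex[i]]
        if (vis < cfg@minVisibleFraction) {
            reasons[i] <- "over_occluded"
        } else if (is.na(mm$match[i]) || mm$iou[i] < cfg@iouMin) {
            reasons[i] <- "poor_localization"
        } else {
            dj <- det[mm$match[i], ]
            confs[i] <- dj$confidence
            if (dj$confidence < cfg@confMin) {
                reasons[i] <- "low_confidence"
            } else if (cfg@requireClassMatch &&
                       dj$class_id != pasted$class_id[i]) {
                reasons[i] <- "class_mismatch"
            } else {
                reasons[i] <- "ok"
            }
        }
    }
    new("ScreeningResult", accepted = all(reasons == "ok"),
        verdicts = data.frame(annIndex = prov$annIndex, reason = reasons,
                              iou = mm$iou, confidence = confs))
}

setMethod("show", "ScreeningResult", function(object) {
    cat(sprintf("ScreeningResult: %s (%s)\n",
                if (object@accepted) "accepted" else "rejected",
                paste(object@verdicts$reason, collapse = ", ")))
})

#' Screen a batch of augmented samples
#'
#' Pure filter: partitions the batch into kept and rejected samples (their
#' union is the input, disjoint) and tallies rejection reasons. The kept
#' stream realizes the quality-controlled augmented distribution.
#'
#' @param samples list of \linkS4class{AugmentedSample}.
#' @param teacher a \linkS4class{TeacherModel}.
#' @param cfg a \linkS4class{ScreeningConfig}.
#' @return list(kept, rejected, results, summary) where \code{summary} is a
#'   named count of rejection reasons over rejected samples plus
#'   \code{n_kept} / \code{n_rejected}.
#' @export
screenBatch <- function(samples, teacher, cfg = screeningConfig()) {
    results <- lapply(samples, screenSample, teacher = teacher, cfg = cfg)
    acc <- vapply(results, function(r) r@accepted, TRUE)
    reasonTab <- c(low_confidence = 0L, poor_localization = 0L,
                   class_mismatch = 0L, over_occluded = 0L)
    for (r in results[!acc]) {
        bad <- r@verdicts$reason[r@verdicts$reason != "ok"]
        # one count per rejected sample, by its first failing reason
        reasonTab[bad[1]] <- reasonTab[bad[1]] + 1L
    }
    list(kept = samples[acc], rejected = samples[!acc], results = results,
         summary = c(as.list(reasonTab),
                     n_kept = sum(acc), n_rejected = sum(!acc)))
}
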