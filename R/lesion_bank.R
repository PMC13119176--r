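# Cosine-feathered rectangular alpha: 1 in the interior, falling smoothly to
# 0 at the crop border over a feather band of 8% of the shorter side (at
# least 1 px). Simple hard overlap introduces boundary artifacts; the soft
# border suppresses them at paste time.
.featherAlpha <- function(h, w, frac = 0.08) {
    f <- max(1L, round(frac * min(h, w)))
    ramp <- function(n) {
        d <- pmin(seq_len(n) - 0.5, n - seq_len(n) + 0.5)
        pmin(1, d / f)
    }
    a <- outer(ramp(h), ramp(w), pmin)
    0.5 * (1 - cos(pi * a))
}

#' Extract donor lesion instances from a dataset
#'
#' Crops every annotated box (expanded by \code{padFraction} of its own size
#' and clipped to the frame) into a \linkS4class{LesionInstance}. The alpha
#' mask is the dataset's ground-truth soft mask when available, otherwise a
#' cosine-feathered rectangle (or a hard all-ones mask with
#' \code{alphaMode = "hard"}). Boxes degenerating below 2x2 px are skipped
#' with a warning, never fatally.
#'
#' @param ds a \linkS4class{DetectionDataset}.
#' @param padFraction box-relative context padding retained around the crop.
#' @param alphaMode "feathered" (default) or "hard".
#' @param classes optional 0-based class ids to restrict extraction to (the
#'   planner only needs donors for deficit classes).
#' @return list of \linkS4class{LesionInstance}.
#' @export
extractInstances <- function(ds, padFraction = 0.05,
                             alphaMode = c("feathered", "hard"),
                             classes = NULL) {
    stopifnot(is(ds, "DetectionDataset"), padFraction >= 0)
    alphaMode <- match.arg(alphaMode)
    out <- list()
    nSkip <- 0L
    for (i in seq_len(nItems(ds))) {
        ann <- ds@annotations[[i]]
        if (nrow(ann) == 0L) next
        keep <- if (is.null(classes)) seq_len(nrow(ann)) else
            which(ann$class_id %in% classes)
        if (length(keep) == 0L) next
        img <- getImage(ds, i)
        H <- dim(img)[1]; W <- dim(img)[2]
        for (j in keep) {
            a <- ann[j, ]
            pw <- a$w * (1 + 2 * padFraction)
            ph <- a$h * (1 + 2 * padFraction)
            px <- .boxToPixels(a$cx, a$cy, min(pw, 1), min(ph, 1), H, W)
            if (length(px$rows) < 2L || length(px$cols) < 2L) {
                nSkip <- nSkip + 1L
                next
            }
            crop <- img[px$rows, px$cols, , drop = FALSE]
            h <- length(px$rows); w <- length(px$cols)
            alpha <- if (length(ds@masks)) {
                m <- ds@masks[[i]][[j]]
                full <- matrix(0, h, w)
                rr <- match(m$rows, px$rows); cc <- match(m$cols, px$cols)
                okr <- !is.na(rr); okc <- !is.na(cc)
                full[rr[okr], cc[okc]] <- m$alpha[okr, okc, drop = FALSE]
                full
            } else if (alphaMode == "feathered") {
                .featherAlpha(h, w)
            } else {
                matrix(1, h, w)
            }
            src <- if (is.character(ds@images[[i]])) ds@images[[i]] else i
            out[[length(out) + 1L]] <- new("LesionInstance",
                pixels = crop, alpha = alpha,
                classId = as.integer(a$class_id),
                source = list(item = src, annIndex = j),
                nativeScale = sqrt(a$w * a$h))
        }
    }
    if (nSkip > 0L)
        warning(nSkip, " degenerate (sub-2-px) box(es) skipped", call. = FALSE)
    out
}

#' Build / query a class-indexed lesion bank
#'
#' \code{buildBank} files extracted instances under their class id;
#' \code{bankCounts} reports per-class availability; \code{sampleInstance}
#' draws uniformly (with the current RNG stream) from one class's list.
#'
#' @param instances list of \linkS4class{LesionInstance}.
#' @param classNames class-name table of the source dataset.
#' @return \code{buildBank}: a \linkS4class{LesionBank}.
#' @export
buildBank <- function(instances, classNames) {
    k <- length(classNames)
    byClass <- rep(list(list()), k)
    for (inst in instances) {
        ix <- inst@classId + 1L
        if (ix > k)
            stop("instance class id ", inst@classId, " exceeds class table")
        byClass[[ix]][[length(byClass[[ix]]) + 1L]] <- inst
    }
    new("LesionBank", instances = byClass, classNames = classNames)
}

#' @rdname buildBank
#' @param bank a \linkS4class{LesionBank}.
#' @export
bankCounts <- function(bank) {
    setNames(vapply(bank@instances, length, 0L), bank@classNames)
}

#' @rdname buildBank
#' @param classId 0-based class to draw from.
#' @export
sampleInstance <- function(bank, classId) {
    lst <- bank@instances[[classId + 1L]]
    if (length(lst) == 0L)
        stop("no donor instances for class ", classId, " ('",
             bank@classNames[classId + 1L], "')")
    lst[[sample.int(length(lst), 1L)]]
}

setMethod("show", "LesionBank", function(object) {
    n <- vapply(object@instances, length, 0L)
    cat(sprintf("LesionBank: %d instance(s) over %d class(es) (%d empty)\n",
                sum(n), length(n), sum(n == 0L)))
})

#' Persist / restore a lesion bank
#'
#' \code{saveBank} writes each crop (and alpha mask) as PNG plus a JSON
#' index carrying class ids, sources and native scales; \code{loadBank}
#' restores the bank from such a directory.
#'
#' @param bank a \linkS4class{LesionBank}.
#' @param dir destination/source directory.
#' @return \code{saveBank}: the index path, invisibly; \code{loadBank}: a
#'   \linkS4class{LesionBank}.
#' @export
saveBank <- function(bank, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    idx <- list(classNames = bank@classNames, entries = list())
    n <- 0L
    for (ci in seq_along(bank@instances)) {
        for (inst in bank@instances[[ci]]) {
            n <- n + 1L
            stem <- sprintf("crop_%05d", n)
            writeImageFile(inst@pixels, file.path(dir, paste0(stem, ".png")))
            png::writePNG(inst@alpha, file.path(dir, paste0(stem, "_a.png")))
            idx$entries[[n]] <- list(stem = stem, class_id = inst@classId,
                                     native_scale = inst@nativeScale,
                                     source = inst@source)
        }
    }
    p <- file.path(dir, "bank_index.json")
    jsonlite::write_json(idx, p, auto_unbox = TRUE, digits = NA)
    invisible(p)
}

#' @rdname saveBank
#' @export
loadBank <- function(dir) {
    idx <- jsonlite::read_json(file.path(dir, "bank_index.json"))
    classNames <- unlist(idx$classNames)
    instances <- lapply(idx$entries, function(e) {
        px <- readImageFile(file.path(dir, paste0(e$stem, ".png")))
        a <- png::readPNG(file.path(dir, paste0(e$stem, "_a.png")))
        if (length(dim(a)) == 3L) a <- a[, , 1]
        new("LesionInstance", pixels = px, alpha = a,
            classId = as.integer(e$class_id),
            source = list(item = e$source$item,
                          annIndex = as.integer(e$source$annIndex)),
            nativeScale = as.numeric(e$native_scale))
    })
    buildBank(instances, classNames)
}
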