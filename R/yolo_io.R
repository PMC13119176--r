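#' Construct a DetectionDataset
#'
#' @param images list of \code{H x W x 3} arrays and/or file paths.
#' @param annotations list of annotation data.frames (columns \code{class_id},
#'   \code{cx}, \code{cy}, \code{w}, \code{h}), parallel to \code{images}.
#' @param classNames character vector of class labels.
#' @param splitTag optional split label ("train", "val" or "test").
#' @param masks optional per-image ground-truth soft masks.
#' @return a \linkS4class{DetectionDataset}.
#' @examples
#' ann <- data.frame(class_id = 0L, cx = .5, cy = .5, w = .2, h = .1)
#' ds <- DetectionDataset(list(array(0.5, c(16, 16, 3))), list(ann), "rust")
#' nItems(ds)
#' @export
DetectionDataset <- function(images, annotations, classNames,
                             splitTag = "", masks = list()) {
    annotations <- lapply(annotations, function(a) {
        a$class_id <- as.integer(a$class_id)
        rownames(a) <- NULL
        a
    })
    new("DetectionDataset", images = images, annotations = annotations,
        classNames = as.character(classNames), splitTag = splitTag,
        masks = masks)
}

#' @rdname accessors
#' @export
setMethod("nItems", "DetectionDataset", function(x) length(x@images))

#' @rdname accessors
#' @param i optional item index; omitted returns the full list.
setMethod("annotations", "DetectionDataset", function(x, i = NULL) {
    if (is.null(i)) x@annotations else x@annotations[[i]]
})

#' @rdname accessors
setMethod("classNames", "DetectionDataset", function(x) x@classNames)

#' @rdname accessors
setMethod("getImage", "DetectionDataset", function(x, i) .asRaster(x@images[[i]]))

setMethod("show", "DetectionDataset", function(object) {
    nb <- sum(vapply(object@annotations, nrow, 0L))
    cat(sprintf("DetectionDataset: %d image(s), %d box(es), %d class(es)%s\n",
                length(object@images), nb, length(object@classNames),
                if (nzchar(object@splitTag))
                    paste0(" [", object@splitTag, "]") else ""))
})

#' Parse one YOLO label line
#'
#' A label line is "class cx cy w h": an integer class index followed by the
#' normalized box center and size. Coordinates outside the unit frame (after
#' allowing boxes clipped exactly to the border) are rejected.
#'
#' @param line character(1).
#' @return one-row annotation data.frame.
#' @examples
#' parseLabelLine("0 0.5 0.5 0.2 0.1")
#' @export
parseLabelLine <- function(line) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 5L)
        stop("malformed label line (need 5 tokens): '", line, "'")
    vals <- suppressWarnings(as.numeric(tok[1:5]))
    if (anyNA(vals))
        stop("non-numeric token in label line: '", line, "'")
    if (vals[1] < 0 || vals[1] != floor(vals[1]))
        stop("class index must be a non-negative integer: '", line, "'")
    ann <- data.frame(class_id = as.integer(vals[1]), cx = vals[2],
                      cy = vals[3], w = vals[4], h = vals[5])
    v <- .validAnnotations(ann)
    if (!isTRUE(v))
        stop("out-of-range coordinate (", v, "): '", line, "'")
    ann
}

#' Format an annotation as a YOLO label line
#'
#' Numbers are printed with 6 decimal places so that write/read round trips
#' are deterministic.
#'
#' @param ann one-row annotation data.frame.
#' @return character(1).
#' @export
formatLabelLine <- function(ann) {
    sprintf("%d %.6f %.6f %.6f %.6f", ann$class_id, ann$cx, ann$cy,
            ann$w, ann$h)
}

.readClassNames <- function(root) {
    for (f in c("classes.txt", "obj.names", "names.txt")) {
        p <- file.path(root, f)
        if (file.exists(p)) {
            nm <- trimws(readLines(p, warn = FALSE))
            return(nm[nzchar(nm)])
        }
    }
    for (f in list.files(root, pattern = "\\.ya?ml$", full.names = TRUE)) {
        y <- tryCatch(yaml::read_yaml(f), error = function(e) NULL)
        if (!is.null(y) && !is.null(y$names)) {
            nm <- y$names
            if (is.list(nm)) nm <- unlist(nm[order(as.integer(names(nm)))])
            return(as.character(nm))
        }
    }
    stop("no class-name file (classes.txt / obj.names / YAML names block) ",
         "found under ", root)
}

#' Read a YOLO-layout dataset from disk
#'
#' Expects image files (\code{images/} subdirectory or the root itself) with
#' same-stem \code{.txt} label files (\code{labels/} subdirectory or
#' alongside), plus a class-name file (\code{classes.txt}, \code{obj.names}
#' or a YAML file with a \code{names} block). Images without a label file are
#' kept as background items with an empty annotation table (a message is
#' emitted). Images are stored as file references and decoded lazily.
#'
#' @param root dataset directory.
#' @return a \linkS4class{DetectionDataset}.
#' @export
readDataset <- function(root) {
    if (!dir.exists(root))
        stop("dataset root not found: ", root)
    classNames <- .readClassNames(root)
    imgDir <- if (dir.exists(file.path(root, "images")))
        file.path(root, "images") else root
    lblDir <- if (dir.exists(file.path(root, "labels")))
        file.path(root, "labels") else imgDir
    imgs <- list.files(imgDir, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                       ignore.case = TRUE, full.names = TRUE)
    if (length(imgs) == 0L)
        stop("no image files under ", imgDir)
    stems <- sub("\\.[^.]+$", "", basename(imgs))
    if (anyDuplicated(stems))
        stop("duplicate image stems: ",
             paste(unique(stems[duplicated(stems)]), collapse = ", "))
    anns <- vector("list", length(imgs))
    nMissing <- 0L
    for (k in seq_along(imgs)) {
        lp <- file.path(lblDir, paste0(stems[k], ".txt"))
        if (!file.exists(lp)) {
            nMissing <- nMissing + 1L
            anns[[k]] <- .emptyAnnotations()
            next
        }
        lines <- readLines(lp, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        anns[[k]] <- if (length(lines) == 0L) .emptyAnnotations() else
            do.call(rbind, lapply(lines, parseLabelLine))
    }
    if (nMissing > 0L)
        message(nMissing, " image(s) without a label file kept as background")
    ds <- DetectionDataset(as.list(imgs), anns, classNames)
    names(ds@images) <- stems
    ds
}

#' Write a dataset in YOLO layout
#'
#' Emits \code{images/<stem>.png}, \code{labels/<stem>.txt} and
#' \code{classes.txt} under \code{root}. In-memory images are encoded as
#' PNG; file-backed images are copied (or re-encoded to PNG if not already
#' PNG). Label numbers are printed with 6 decimals.
#'
#' @param ds a \linkS4class{DetectionDataset}.
#' @param root destination directory (created if missing).
#' @param overwrite allow writing over existing files.
#' @return invisibly, a character vector manifest of the files written.
#' @export
writeDataset <- function(ds, root, overwrite = FALSE) {
    stopifnot(is(ds, "DetectionDataset"))
    if (nItems(ds) == 0L)
        return(invisible(character()))
    dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "labels"), recursive = TRUE, showWarnings = FALSE)
    stems <- names(ds@images)
    if (is.null(stems) || any(!nzchar(stems)))
        stems <- sprintf("item_%05d", seq_len(nItems(ds)))
    manifest <- character()
    for (k in seq_len(nItems(ds))) {
        ip <- file.path(root, "images", paste0(stems[k], ".png"))
        lp <- file.path(root, "labels", paste0(stems[k], ".txt"))
        if (!overwrite && (file.exists(ip) || file.exists(lp)))
            stop("refusing to overwrite existing file for stem '", stems[k],
                 "' (set overwrite = TRUE)")
        src <- ds@images[[k]]
        if (is.character(src) && grepl("\\.png$", src, ignore.case = TRUE)) {
            file.copy(src, ip, overwrite = overwrite)
        } else {
            writeImageFile(.asRaster(src), ip)
        }
        ann <- ds@annotations[[k]]
        lines <- if (nrow(ann)) vapply(seq_len(nrow(ann)), function(j)
            formatLabelLine(ann[j, ]), "") else character()
        writeLines(lines, lp)
        manifest <- c(manifest, ip, lp)
    }
    cp <- file.path(root, "classes.txt")
    writeLines(ds@classNames, cp)
    invisible(c(manifest, cp))
}

#' Stratified train/val/test split
#'
#' Each image is assigned a stratum: the majority class among its boxes (ties
#' broken by the lowest class id); images without boxes form a background
#' stratum. Within each stratum images are shuffled deterministically and
#' allocated to the three splits by largest-remainder apportionment, so every
#' split's per-stratum size is within one image of the exact proportion.
#'
#' @param ds a \linkS4class{DetectionDataset}.
#' @param ratios numeric(3) summing to 1; default the 8:1:1 convention.
#' @param seed integer RNG seed.
#' @return named list of three \linkS4class{DetectionDataset}s
#'   (\code{train}, \code{val}, \code{test}), tagged accordingly.
#' @export
stratifiedSplit <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
    stopifnot(is(ds, "DetectionDataset"))
    if (nItems(ds) == 0L)
        stop("cannot split an empty dataset")
    if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
        stop("ratios must be three fractions summing to 1")
    stratum <- vapply(ds@annotations, function(a) {
        if (nrow(a) == 0L) return(-1L)
        tab <- table(a$class_id)
        cand <- as.integer(names(tab)[tab == max(tab)])
        min(cand)
    }, 0L)
    assign <- integer(nItems(ds))
    set.seed(.stageSeed(seed, "stratified_split"))
    for (s in sort(unique(stratum))) {
        idx <- which(stratum == s)
        idx <- idx[sample.int(length(idx))]
        n <- length(idx)
        base <- floor(n * ratios)
        rem <- n * ratios - base
        extra <- n - sum(base)
        if (extra > 0) {
            ord <- order(rem, decreasing = TRUE)
            base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
        }
        splitId <- rep.int(1:3, base)
        assign[idx] <- splitId
    }
    out <- lapply(1:3, function(k) {
        sel <- which(assign == k)
        DetectionDataset(ds@images[sel], ds@annotations[sel], ds@classNames,
                         splitTag = c("train", "val", "test")[k],
                         masks = if (length(ds@masks)) ds@masks[sel]
                                 else list())
    })
    names(out) <- c("train", "val", "test")
    out
}
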