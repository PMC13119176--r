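#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom grDevices col2rgb hsv
NULL

.validAnnotations <- function(ann) {
    need <- c("class_id", "cx", "cy", "w", "h")
    if (!is.data.frame(ann))
        return("annotations must be a data.frame")
    if (!all(need %in% names(ann)))
        return(paste0("annotation table lacks columns: ",
                      paste(setdiff(need, names(ann)), collapse = ", ")))
    if (nrow(ann) == 0L)
        return(TRUE)
    eps <- 1e-6
    if (any(ann$class_id < 0L) || any(ann$class_id != floor(ann$class_id)))
        return("class_id must be a non-negative integer")
    if (any(ann$cx < 0 | ann$cx > 1 | ann$cy < 0 | ann$cy > 1))
        return("box centers must lie in [0, 1]")
    if (any(ann$w <= 0 | ann$w > 1 | ann$h <= 0 | ann$h > 1))
        return("box sizes must lie in (0, 1]")
    if (any(ann$cx - ann$w / 2 < -eps | ann$cx + ann$w / 2 > 1 + eps |
            ann$cy - ann$h / 2 < -eps | ann$cy + ann$h / 2 > 1 + eps))
        return("boxes must be clipped to the frame")
    TRUE
}

#' DetectionDataset: images with YOLO-style annotations
#'
#' Container for an object-detection dataset: a list of images (in-memory
#' \code{H x W x 3} arrays with values in \code{[0, 1]}, or file paths loaded
#' lazily), one annotation table per image, and the ordered class-name table
#' that the integer class ids index into.
#'
#' Each annotation table is a data.frame with columns \code{class_id}
#' (0-based integer), \code{cx}, \code{cy} (normalized box center) and
#' \code{w}, \code{h} (normalized box size), the YOLO label convention.
#'
#' @slot images list; each element a numeric array or a character path.
#' @slot annotations list of data.frames, parallel to \code{images}.
#' @slot classNames character vector of class labels.
#' @slot splitTag character; one of \code{""}, \code{"train"}, \code{"val"},
#'   \code{"test"}.
#' @slot masks optional ground-truth soft masks: either empty, or one list
#'   per image holding, per annotation, a list with \code{rows}, \code{cols}
#'   (pixel extents) and \code{alpha} (matrix in [0, 1]).
#' @exportClass DetectionDataset
setClass("DetectionDataset",
    representation(images = "list", annotations = "list",
                   classNames = "character", splitTag = "character",
                   masks = "list"),
    prototype(images = list(), annotations = list(),
              classNames = character(), splitTag = "", masks = list()))

setValidity("DetectionDataset", function(object) {
    if (length(object@images) != length(object@annotations))
        return("images and annotations must have equal length")
    if (length(object@masks) > 0L &&
        length(object@masks) != length(object@images))
        return("masks, when present, must have one entry per image")
    if (length(object@splitTag) != 1L ||
        !object@splitTag %in% c("", "train", "val", "test"))
        return("splitTag must be one of '', 'train', 'val', 'test'")
    for (i in seq_along(object@annotations)) {
        v <- .validAnnotations(object@annotations[[i]])
        if (!isTRUE(v))
            return(sprintf("item %d: %s", i, v))
        cid <- object@annotations[[i]]$class_id
        if (length(cid) && any(cid >= length(object@classNames)))
            return(sprintf("item %d: class_id exceeds class table", i))
    }
    TRUE
})

#' ClassDistribution: per-class instance counts
#'
#' The count vector \eqn{N = (N_1, \dots, N_k)} of object instances per
#' class, the quantity every long-tail diagnostic is computed from. Counts
#' are instance (bounding-box) counts, not image counts.
#'
#' @slot counts non-negative integer vector, one entry per class.
#' @slot classNames character vector parallel to \code{counts}.
#' @exportClass ClassDistribution
setClass("ClassDistribution",
    representation(counts = "integer", classNames = "character"))

setValidity("ClassDistribution", function(object) {
    if (length(object@counts) < 1L)
        return("at least one class required")
    if (length(object@counts) != length(object@classNames))
        return("counts and classNames must have equal length")
    if (any(object@counts < 0L))
        return("counts must be non-negative")
    TRUE
})

#' DistributionReport: long-tail diagnostics of a dataset
#'
#' Holds the imbalance ratio (max/min positive class count), the population
#' standard deviation of log counts, effective-category coverage and
#' effective-sample proportion at threshold \code{n0}, and normalized
#' histograms of box centers and of box scales \eqn{\sqrt{wh}}.
#'
#' @slot distribution a \linkS4class{ClassDistribution}.
#' @slot imbalanceRatio numeric \eqn{\ge 1}.
#' @slot logDispersion numeric \eqn{\ge 0}.
#' @slot n0 integer threshold for "effective" classes.
#' @slot effectiveCount integer; classes with count \eqn{\ge n0}.
#' @slot effectiveFraction numeric; \code{effectiveCount / nClasses}.
#' @slot effectiveSampleFraction numeric; share of instances in effective
#'   classes.
#' @slot centerHistogram numeric matrix (rows = cy bins, cols = cx bins)
#'   summing to 1, or a 0x0 matrix when the dataset has no boxes.
#' @slot scaleHistogram numeric vector over \eqn{\sqrt{wh}} summing to 1, or
#'   length 0 when there are no boxes.
#' @exportClass DistributionReport
setClass("DistributionReport",
    representation(distribution = "ClassDistribution",
                   imbalanceRatio = "numeric", logDispersion = "numeric",
                   n0 = "integer", effectiveCount = "integer",
                   effectiveFraction = "numeric",
                   effectiveSampleFraction = "numeric",
                   centerHistogram = "matrix", scaleHistogram = "numeric"))

#' LesionInstance: an extracted object crop
#'
#' A donor object for copy-paste: the pixel crop (box plus optional padding),
#' a soft alpha mask in \code{[0, 1]}, the class id, a reference back to the
#' source image/annotation, and the object's native normalized scale
#' \eqn{\sqrt{wh}} in its source frame.
#'
#' @slot pixels numeric array \code{h x w x 3}.
#' @slot alpha numeric matrix \code{h x w} in \code{[0, 1]}.
#' @slot classId integer (0-based).
#' @slot source list with elements \code{item} (image index or path) and
#'   \code{annIndex}.
#' @slot nativeScale numeric in (0, 1].
#' @exportClass LesionInstance
setClass("LesionInstance",
    representation(pixels = "array", alpha = "matrix", classId = "integer",
                   source = "list", nativeScale = "numeric"))

setValidity("LesionInstance", function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
        return("pixels must be an h x w x 3 array")
    if (d[1] < 2L || d[2] < 2L)
        return("crop must be at least 2 x 2 px")
    if (!identical(dim(object@alpha), d[1:2]))
        return("alpha must match the crop's spatial shape")
    if (any(object@alpha < 0 | object@alpha > 1))
        return("alpha values must lie in [0, 1]")
    if (object@nativeScale <= 0 || object@nativeScale > 1)
        return("nativeScale must lie in (0, 1]")
    TRUE
})

#' LesionBank: class-indexed donor instances
#'
#' @slot instances list of length nClasses; element \code{i} is a list of
#'   \linkS4class{LesionInstance} objects of class id \code{i - 1}.
#' @slot classNames character vector.
#' @exportClass LesionBank
setClass("LesionBank",
    representation(instances = "list", classNames = "character"))

setValidity("LesionBank", function(object) {
    if (length(object@instances) != length(object@classNames))
        return("instances must have one slot per class")
    for (i in seq_along(object@instances)) {
        for (inst in object@instances[[i]]) {
            if (!is(inst, "LesionInstance"))
                return("bank entries must be LesionInstance objects")
            if (inst@classId != i - 1L)
                return(sprintf("instance filed under wrong class (%d)", i - 1L))
        }
    }
    TRUE
})

#' AugmentedSample: one synthesized training image
#'
#' An image after copy-paste and environment simulation, its full annotation
#' table (originals first, pasted boxes appended), per-pasted-box provenance,
#' and per-box visible fractions after occlusion.
#'
#' @slot image numeric array \code{H x W x 3}.
#' @slot annotations annotation data.frame (see
#'   \linkS4class{DetectionDataset}).
#' @slot provenance data.frame with one row per pasted box: \code{annIndex}
#'   (row in \code{annotations}), donor source, placement center, scale
#'   factor, blend mode, effects applied.
#' @slot visibleFraction numeric vector, one entry per annotation row.
#' @slot pendingScreen logical; TRUE until the teacher screen has run.
#' @exportClass AugmentedSample
setClass("AugmentedSample",
    representation(image = "array", annotations = "data.frame",
                   provenance = "data.frame", visibleFraction = "numeric",
                   pendingScreen = "logical"))

setValidity("AugmentedSample", function(object) {
    v <- .validAnnotations(object@annotations)
    if (!isTRUE(v)) return(v)
    if (nrow(object@provenance) > 0) {
        if (!"annIndex" %in% names(object@provenance))
            return("provenance must carry annIndex")
        if (any(object@provenance$annIndex > nrow(object@annotations)))
            return("provenance annIndex out of range")
    }
    if (length(object@visibleFraction) != nrow(object@annotations))
        return("visibleFraction must have one entry per annotation")
    TRUE
})

#' ScreeningResult: accept/reject verdict for one augmented sample
#'
#' @slot accepted logical; TRUE iff every pasted box's verdict is "ok".
#' @slot verdicts data.frame with columns \code{annIndex}, \code{reason}
#'   (one of ok, low_confidence, poor_localization, class_mismatch,
#'   over_occluded), \code{iou}, \code{confidence}.
#' @exportClass ScreeningResult
setClass("ScreeningResult",
    representation(accepted = "logical", verdicts = "data.frame"))

setValidity("ScreeningResult", function(object) {
    ok <- nrow(object@verdicts) == 0L || all(object@verdicts$reason == "ok")
    if (!identical(object@accepted, ok))
        return("accepted must equal 'every pasted-box verdict is ok'")
    TRUE
})

#' TeacherModel: detector interface for accept-reject screening
#'
#' Virtual parent class. A concrete teacher implements
#' \code{\link{predictBoxes}}, returning for an image a data.frame of
#' detections with columns \code{class_id}, \code{cx}, \code{cy}, \code{w},
#' \code{h}, \code{confidence}. The package ships two concrete teachers:
#' \linkS4class{OracleTeacher} (ground-truth-aware test double) and
#' \linkS4class{FunctionTeacher} (adapter around a user function).
#'
#' @exportClass TeacherModel
setClass("TeacherModel", representation("VIRTUAL"))

#' OracleTeacher: ground-truth-based teacher test double
#'
#' Simulates a detector of controllable quality on samples whose ground truth
#' is known: each true box is detected independently with probability
#' \code{detectionProb}; a detected box is reported with Gaussian pixel
#' jitter of scale \code{locNoise} (in pixels) and confidence drawn from
#' \code{N(confBase, confSd)} truncated to \code{[0, 1]}. With
#' \code{detectionProb = 1}, \code{locNoise = 0}, \code{confSd = 0} and
#' \code{confBase = 1} its predictions equal the ground truth with
#' confidence 1.
#'
#' @slot detectionProb numeric in [0, 1].
#' @slot confBase numeric in [0, 1].
#' @slot confSd numeric >= 0.
#' @slot locNoise numeric >= 0, pixel jitter s.d.
#' @exportClass OracleTeacher
setClass("OracleTeacher", contains = "TeacherModel",
    representation(detectionProb = "numeric", confBase = "numeric",
                   confSd = "numeric", locNoise = "numeric"))

setValidity("OracleTeacher", function(object) {
    if (object@detectionProb < 0 || object@detectionProb > 1)
        return("detectionProb must lie in [0, 1]")
    if (object@confBase < 0 || object@confBase > 1)
        return("confBase must lie in [0, 1]")
    if (object@confSd < 0 || object@locNoise < 0)
        return("confSd and locNoise must be non-negative")
    TRUE
})

#' FunctionTeacher: adapter wrapping an arbitrary prediction function
#'
#' @slot fn function(image, annotations) returning a detection data.frame
#'   with columns class_id, cx, cy, w, h, confidence.
#' @exportClass FunctionTeacher
setClass("FunctionTeacher", contains = "TeacherModel",
    representation(fn = "function"))
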