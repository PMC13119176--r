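#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: number of items,
#' annotation tables, class-name table, per-class counts, and lazy image
#' retrieval.
#'
#' @param x,object an object of one of the package's S4 classes.
#' @param i integer index of the item.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x, ...) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' Run a teacher detector on an image
#'
#' Dispatches on the teacher class. Returns a data.frame of detections with
#' columns \code{class_id}, \code{cx}, \code{cy}, \code{w}, \code{h},
#' \code{confidence} (possibly zero rows). The \code{truth} argument carries
#' the sample's ground-truth annotation table; the
#' \linkS4class{OracleTeacher} bases its simulated detections on it, while
#' adapters around real detectors are free to ignore it.
#'
#' @param teacher a \linkS4class{TeacherModel}.
#' @param image numeric \code{H x W x 3} array in [0, 1].
#' @param truth ground-truth annotation data.frame (may be ignored).
#' @return data.frame of detections.
#' @export
setGeneric("predictBoxes", function(teacher, image, truth)
    standardGeneric("predictBoxes"))
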