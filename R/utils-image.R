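# Internal raster helpers. Images are numeric arrays [H, W, 3] with values in
# [0, 1]; row 1 is the top of the frame, column 1 the left edge. EBImage keeps
# its Image objects transposed (x before y), hence the aperm at call sites.

.asRaster <- function(img) {
    if (is.character(img))
        img <- readImageFile(img)
    d <- dim(img)
    if (is.null(d) || length(d) < 2L)
        stop("image must be a 2- or 3-dimensional array")
    if (length(d) == 2L)
        img <- array(rep(img, 3L), dim = c(d, 3L))
    if (dim(img)[3] > 3L)
        img <- img[, , 1:3, drop = FALSE]
    img
}

#' Read an image file into an H x W x 3 array
#'
#' PNG is read natively; other formats (JPEG, TIFF) are delegated to
#' \code{EBImage::readImage}. Grayscale inputs are expanded to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return numeric array \code{H x W x 3} with values in [0, 1].
#' @export
readImageFile <- function(path) {
    if (!file.exists(path))
        stop("image file not found: ", path)
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        img <- png::readPNG(path)
    } else {
        eb <- EBImage::readImage(path)
        a <- EBImage::imageData(eb)
        img <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }
    .asRaster(img)
}

#' Write an H x W x 3 array as PNG
#'
#' @param img numeric array in [0, 1].
#' @param path destination; parent directory must exist.
#' @return \code{path}, invisibly.
#' @export
writeImageFile <- function(img, path) {
    img <- .asRaster(img)
    png::writePNG(pmin(pmax(img, 0), 1), path)
    invisible(path)
}

# EBImage round trips: [H, W, 3] <-> Image (x = width first)
.toEB <- function(img)
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
.fromEB <- function(eb)
    aperm(EBImage::imageData(eb), c(2L, 1L, 3L))

# Bilinear resize to target height/width.
.resizeRaster <- function(img, h, w) {
    d <- dim(img)
    if (d[1] == h && d[2] == w)
        return(img)
    out <- .fromEB(EBImage::resize(.toEB(img), w = w, h = h))
    pmin(pmax(out, 0), 1)
}

.resizeMatrix <- function(m, h, w) {
    if (nrow(m) == h && ncol(m) == w)
        return(m)
    out <- t(EBImage::imageData(EBImage::resize(
        EBImage::Image(t(m)), w = w, h = h)))
    pmin(pmax(out, 0), 1)
}

# Pixel extent of a normalized box in an H x W frame: half-open [x0, x1) in
# continuous pixel coordinates, then the covered 1-based pixel rows/cols.
.boxToPixels <- function(cx, cy, w, h, H, W) {
    x0 <- (cx - w / 2) * W; x1 <- (cx + w / 2) * W
    y0 <- (cy - h / 2) * H; y1 <- (cy + h / 2) * H
    cols <- max(1L, floor(x0) + 1L):min(W, ceiling(x1))
    rows <- max(1L, floor(y0) + 1L):min(H, ceiling(y1))
    list(rows = rows, cols = cols)
}

# Normalized box from a covered pixel extent.
.pixelsToBox <- function(rows, cols, H, W) {
    x0 <- (min(cols) - 1) / W; x1 <- max(cols) / W
    y0 <- (min(rows) - 1) / H; y1 <- max(rows) / H
    list(cx = (x0 + x1) / 2, cy = (y0 + y1) / 2, w = x1 - x0, h = y1 - y0)
}

.emptyAnnotations <- function() {
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
}

# Filled-ellipse mask on an h x w grid: center (rc, cc), semi-axes (ra, ca)
# in pixels, optionally rotated by theta.
.ellipseMask <- function(h, w, rc, cc, ra, ca, theta = 0) {
    r <- matrix(seq_len(h), h, w) - rc
    c <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
    if (theta != 0) {
        rr <- r * cos(theta) - c * sin(theta)
        cc2 <- r * sin(theta) + c * cos(theta)
        r <- rr; c <- cc2
    }
    (r / ra)^2 + (c / ca)^2 <= 1
}

# Derive a 32-bit stage seed from a base seed and a stage label so that
# stages draw from independent streams regardless of call order.
.stageSeed <- function(seed, stage) {
    hv <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + hv * 104729) %% 2147483647)
}
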