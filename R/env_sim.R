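#' EnvProfile: multi-stage environment simulation settings
#'
#' Configures the three visibility-degradation stages applied to augmented
#' samples, in fixed order: luminance perturbation, adverse-weather effects
#' (fog, rain, blur), then physical occlusion (last, so the per-box
#' visibility accounting reflects the final raster). Every effect at zero
#' intensity or zero probability is the bit-exact identity.
#'
#' @slot luminance list(range = numeric(2) multiplicative gain bounds,
#'   prob = application probability).
#' @slot weather list of list(kind = "fog"|"rain"|"blur",
#'   range = numeric(2) intensity bounds in [0, 1], prob).
#' @slot occlusion list(countRange = integer(2), sizeRange = numeric(2)
#'   occluder side as fraction of the frame, maxBoxOcclusion = maximum
#'   tolerated occluded fraction of any pasted box, prob).
#' @exportClass EnvProfile
setClass("EnvProfile",
    representation(luminance = "list", weather = "list",
                   occlusion = "list"))

#' @param lumRange,lumProb luminance gain range and probability.
#' @param weather list of weather effects (kind, range, prob); default fog,
#'   rain and blur each at moderate intensity with probability 0.3.
#' @param occCountRange,occSizeRange,maxBoxOcclusion,occProb occluder count
#'   and size ranges, per-pasted-box occlusion cap, application probability.
#' @return an \linkS4class{EnvProfile}.
#' @rdname EnvProfile-class
#' @export
envProfile <- function(lumRange = c(0.4, 1.6), lumProb = 0.8,
                       weather = list(
                           list(kind = "fog", range = c(0.2, 0.7), prob = 0.3),
                           list(kind = "rain", range = c(0.2, 0.8), prob = 0.3),
                           list(kind = "blur", range = c(0.1, 0.5), prob = 0.3)),
                       occCountRange = c(1L, 3L), occSizeRange = c(0.08, 0.2),
                       maxBoxOcclusion = 0.5, occProb = 0.5) {
    stopifnot(lumRange[1] > 0, lumProb >= 0, lumProb <= 1,
              maxBoxOcclusion >= 0, maxBoxOcclusion < 1)
    for (wx in weather)
        stopifnot(wx$kind %in% c("fog", "rain", "blur"),
                  wx$prob >= 0, wx$prob <= 1)
    new("EnvProfile",
        luminance = list(range = as.numeric(lumRange), prob = lumProb),
        weather = weather,
        occlusion = list(countRange = as.integer(occCountRange),
                         sizeRange = as.numeric(occSizeRange),
                         maxBoxOcclusion = maxBoxOcclusion, prob = occProb))
}

#' Luminance perturbation
#'
#' Per-pixel multiplicative gain with clipping to [0, 1]; gain 1 is the
#' bit-exact identity.
#'
#' @param img numeric \code{H x W x 3} array in [0, 1].
#' @param gain positive multiplicative factor.
#' @return perturbed image.
#' @export
luminancePerturb <- function(img, gain) {
    if (gain <= 0)
        stop("gain must be positive")
    if (gain == 1)
        return(img)
    pmin(pmax(img * gain, 0), 1)
}

.fog <- function(img, intensity) {
    S <- dim(img)[1:2]
    veil <- 0.85 + .resizeMatrix(matrix(runif(36, -0.03, 0.03), 6, 6),
                                 S[1], S[2])
    a <- 0.8 * intensity
    out <- img
    for (ch in 1:3)
        out[, , ch] <- img[, , ch] * (1 - a) + veil * a
    pmin(pmax(out, 0), 1)
}

.rain <- function(img, intensity) {
    H <- dim(img)[1]; W <- dim(img)[2]
    n <- round(8 + 70 * intensity)
    for (k in seq_len(n)) {
        len <- max(3L, round(H * runif(1, 0.08, 0.08 + 0.2 * intensity)))
        theta <- (70 + runif(1, -10, 10)) * pi / 180
        r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
        t <- seq(0, len, by = 0.7)
        rr <- round(r0 + t * sin(theta)); cc <- round(c0 + t * cos(theta))
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        rr <- rr[ok]; cc <- cc[ok]
        if (!length(rr)) next
        idx <- cbind(rr, cc)
        mix <- 0.35 + 0.3 * intensity
        for (ch in 1:3) {
            plane <- img[, , ch]
            plane[idx] <- plane[idx] * (1 - mix) + 1 * mix
            img[, , ch] <- plane
        }
    }
    img
}

.blur <- function(img, intensity) {
    sigma <- 3 * intensity
    .fromEB(EBImage::gblur(.toEB(img), sigma = sigma))
}

#' Adverse-weather simulation
#'
#' Applies one weather effect at the given intensity. Intensity 0 is the
#' bit-exact identity for every kind. \code{fog} alpha-blends the image
#' toward a light-gray veil with low-frequency spatial noise (reducing
#' contrast); \code{rain} overlays oriented bright streaks; \code{blur} is a
#' Gaussian blur with sigma = 3 * intensity pixels (so repeated blurs
#' compose with sigmas adding in quadrature).
#'
#' @param img numeric \code{H x W x 3} array in [0, 1].
#' @param kind one of "fog", "rain", "blur".
#' @param intensity in [0, 1].
#' @return perturbed image.
#' @export
weatherSim <- function(img, kind, intensity) {
    stopifnot(intensity >= 0, intensity <= 1)
    if (intensity == 0)
        return(img)
    switch(kind,
           fog = .fog(img, intensity),
           rain = .rain(img, intensity),
           blur = .blur(img, intensity),
           stop("unknown weather kind: ", kind))
}

# Rasterize one random occluder (dark ellipse or rectangle) onto mask/img.
.drawOccluder <- function(H, W, sizeRange) {
    side <- runif(1, sizeRange[1], sizeRange[2]) * min(H, W)
    rc <- runif(1, 1, H); cc <- runif(1, 1, W)
    if (runif(1) < 0.5) {
        m <- .ellipseMask(H, W, rc, cc, side / 2 * runif(1, 0.6, 1.4),
                          side / 2 * runif(1, 0.6, 1.4), runif(1, 0, pi))
    } else {
        m <- matrix(FALSE, H, W)
        rows <- max(1, round(rc - side / 2)):min(H, round(rc + side / 2))
        cols <- max(1, round(cc - side / 2)):min(W, round(cc + side / 2))
        m[rows, cols] <- TRUE
    }
    list(mask = m, shade = runif(1, 0.02, 0.15))
}

#' Physical occlusion with visibility accounting
#'
#' Draws random dark elliptical/rectangular occluders over the image and
#' computes, for every annotation, the visible fraction of its box from the
#' occluder raster (pixel counting, so arbitrary occluder shapes are handled
#' consistently). If any box listed in \code{pastedIdx} would end up with an
#' occluded fraction above \code{maxBoxOcclusion}, the whole occluder set is
#' redrawn (bounded retries); on exhaustion the effect is skipped.
#'
#' @param img numeric \code{H x W x 3} array.
#' @param ann annotation data.frame.
#' @param pastedIdx annotation row indices whose occlusion is capped.
#' @param countRange,sizeRange,maxBoxOcclusion see
#'   \linkS4class{EnvProfile}.
#' @param maxRetries redraw attempts before skipping the effect.
#' @return list(image, visibleFraction, applied).
#' @export
occlude <- function(img, ann, pastedIdx = integer(),
                    countRange = c(1L, 3L), sizeRange = c(0.08, 0.2),
                    maxBoxOcclusion = 0.5, maxRetries = 10L) {
    H <- dim(img)[1]; W <- dim(img)[2]
    for (try in seq_len(maxRetries)) {
        n <- sample(countRange[1]:countRange[2], 1L)
        occs <- lapply(seq_len(n), function(k)
            .drawOccluder(H, W, sizeRange))
        mask <- if (n == 0L) matrix(FALSE, H, W) else
            Reduce(`|`, lapply(occs, `[[`, "mask"))
        vf <- visibleFractions(mask, ann)
        if (length(pastedIdx) == 0L ||
            all(vf[pastedIdx] >= 1 - maxBoxOcclusion)) {
            for (oc in occs) {
                for (ch in 1:3) {
                    plane <- img[, , ch]
                    plane[oc$mask] <- oc$shade
                    img[, , ch] <- plane
                }
            }
            return(list(image = img, visibleFraction = vf, applied = TRUE))
        }
    }
    message("occlusion retries exhausted; effect skipped")
    list(image = img, visibleFraction = rep(1, nrow(ann)), applied = FALSE)
}

#' Per-box visible fractions from an occluder raster
#'
#' For every annotated box, the fraction of its pixel area not covered by
#' the occluder mask. Pixel counting on the raster keeps the accounting
#' exact for arbitrary occluder shapes.
#'
#' @param mask logical \code{H x W} matrix (TRUE = occluded).
#' @param ann annotation data.frame.
#' @return numeric vector in [0, 1], one entry per annotation.
#' @export
visibleFractions <- function(mask, ann) {
    H <- nrow(mask); W <- ncol(mask)
    vapply(seq_len(nrow(ann)), function(j) {
        px <- .boxToPixels(ann$cx[j], ann$cy[j], ann$w[j], ann$h[j], H, W)
        1 - sum(mask[px$rows, px$cols]) /
            (length(px$rows) * length(px$cols))
    }, 0)
}

#' Apply the full environment stage to an augmented sample
#'
#' Fixed order luminance -> weather -> occlusion; each stage fires with its
#' profile probability using the current RNG stream. Annotation geometry is
#' never altered, only pixels and visibility metadata; applied effects are
#' recorded in the provenance table.
#'
#' @param sample an \linkS4class{AugmentedSample}.
#' @param profile an \linkS4class{EnvProfile}, or \code{NULL} for a no-op.
#' @return the transformed sample.
#' @export
applyEnvironment <- function(sample, profile) {
    if (is.null(profile))
        return(sample)
    stopifnot(is(sample, "AugmentedSample"), is(profile, "EnvProfile"))
    img <- sample@image
    applied <- character()
    lum <- profile@luminance
    if (runif(1) < lum$prob) {
        g <- runif(1, lum$range[1], lum$range[2])
        img <- luminancePerturb(img, g)
        applied <- c(applied, sprintf("luminance:%.3f", g))
    }
    for (wx in profile@weather) {
        if (runif(1) < wx$prob) {
            it <- runif(1, wx$range[1], wx$range[2])
            img <- weatherSim(img, wx$kind, it)
            applied <- c(applied, sprintf("%s:%.3f", wx$kind, it))
        }
    }
    vf <- sample@visibleFraction
    occ <- profile@occlusion
    if (runif(1) < occ$prob && nrow(sample@annotations) > 0L) {
        res <- occlude(img, sample@annotations,
                       pastedIdx = sample@provenance$annIndex,
                       countRange = occ$countRange,
                       sizeRange = occ$sizeRange,
                       maxBoxOcclusion = occ$maxBoxOcclusion)
        if (res$applied) {
            img <- res$image
            vf <- res$visibleFraction
            applied <- c(applied, "occlusion")
        }
    }
    sample@image <- img
    sample@visibleFraction <- vf
    if (nrow(sample@provenance))
        sample@provenance$effects <- paste(applied, collapse = ";")
    sample
}
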