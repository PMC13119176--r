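#' Per-class instance counts of a dataset
#'
#' Counts bounding-box instances (not images) per class, the vector
#' \eqn{N = (N_1, \dots, N_k)} all long-tail diagnostics operate on.
#'
#' @param x a \linkS4class{DetectionDataset}, or an integer count vector.
#' @param classNames class labels when \code{x} is a plain vector.
#' @return a \linkS4class{ClassDistribution}.
#' @examples
#' classDistribution(c(755, 30, 2), c("head", "mid", "tail"))
#' @export
classDistribution <- function(x, classNames = NULL) {
    if (is(x, "DetectionDataset")) {
        k <- length(x@classNames)
        cnt <- integer(k)
        for (a in x@annotations) {
            if (nrow(a))
                for (cid in a$class_id) cnt[cid + 1L] <- cnt[cid + 1L] + 1L
        }
        return(new("ClassDistribution", counts = cnt,
                   classNames = x@classNames))
    }
    cnt <- as.integer(x)
    if (is.null(classNames))
        classNames <- sprintf("class_%02d", seq_along(cnt) - 1L)
    new("ClassDistribution", counts = cnt, classNames = classNames)
}

#' @rdname accessors
#' @export
setMethod("counts", "ClassDistribution", function(x) {
    setNames(x@counts, x@classNames)
})

#' @rdname accessors
setMethod("classNames", "ClassDistribution", function(x) x@classNames)

setMethod("show", "ClassDistribution", function(object) {
    cat(sprintf("ClassDistribution: %d classes, %d instances (min %d, max %d)\n",
                length(object@counts), sum(object@counts),
                min(object@counts), max(object@counts)))
})

.positiveCounts <- function(d, what) {
    cnt <- if (is(d, "ClassDistribution")) d@counts else as.numeric(d)
    pos <- cnt[cnt > 0]
    if (length(pos) < length(cnt))
        message(length(cnt) - length(pos),
                " zero-count class(es) excluded from ", what)
    pos
}

#' Imbalance ratio
#'
#' The ratio of the largest to the smallest per-class sample count,
#' \eqn{IR = \max_i N_i / \min_i N_i}; 1 means a perfectly balanced
#' distribution. Zero-count classes are excluded from the minimum (with a
#' message) rather than producing an infinite ratio.
#'
#' @param d a \linkS4class{ClassDistribution} or count vector.
#' @return numeric \eqn{\ge 1}.
#' @examples
#' imbalanceRatio(c(755, 120, 2))   # 377.5
#' @export
imbalanceRatio <- function(d) {
    pos <- .positiveCounts(d, "imbalance ratio")
    if (length(pos) == 0L)
        stop("imbalance ratio undefined: all counts are zero")
    max(pos) / min(pos)
}

#' Log-scale dispersion of class frequencies
#'
#' Population standard deviation of the log counts: a scale-free measure of
#' multiplicative spread, invariant under multiplying every count by a
#' constant (so it is comparable before and after augmentation despite the
#' change in total volume). Natural log by default; the base is configurable
#' since it only rescales the value.
#'
#' @param d a \linkS4class{ClassDistribution} or count vector.
#' @param base logarithm base (default \code{exp(1)}).
#' @return numeric \eqn{\ge 0}.
#' @export
logDispersion <- function(d, base = exp(1)) {
    pos <- .positiveCounts(d, "log dispersion")
    if (length(pos) < 2L)
        stop("log dispersion needs at least 2 positive classes")
    lg <- log(pos, base = base)
    sqrt(mean((lg - mean(lg))^2))
}

#' Effective-category coverage
#'
#' Classes with at least \code{n0} samples are "effective": large enough to
#' support stable gradient learning. Returns how many classes qualify and the
#' fraction of the class table they represent.
#'
#' @param d a \linkS4class{ClassDistribution} or count vector.
#' @param n0 integer threshold (the convention in the diagnostics is 200).
#' @return list with elements \code{count} and \code{fraction}.
#' @examples
#' effectiveCoverage(c(250, 300, 10), n0 = 200)  # 2 of 3
#' @export
effectiveCoverage <- function(d, n0 = 200L) {
    stopifnot(n0 >= 0)
    cnt <- if (is(d, "ClassDistribution")) d@counts else as.numeric(d)
    k <- sum(cnt >= n0)
    list(count = as.integer(k), fraction = k / length(cnt))
}

#' Effective-sample proportion
#'
#' The share of all instances that belong to effective classes (count
#' \eqn{\ge n0}): the fraction of gradient signal coming from classes with
#' enough support to learn stably.
#'
#' @inheritParams effectiveCoverage
#' @return numeric in [0, 1].
#' @export
effectiveSampleProportion <- function(d, n0 = 200L) {
    stopifnot(n0 >= 0)
    cnt <- if (is(d, "ClassDistribution")) d@counts else as.numeric(d)
    tot <- sum(cnt)
    if (tot <= 0)
        stop("effective-sample proportion undefined for an empty distribution")
    sum(cnt[cnt >= n0]) / tot
}

# Half-open binning on [0, 1]: values on an interior edge go up, the final
# bin is closed at 1.
.binIndex <- function(v, bins) {
    pmin(bins, floor(v * bins) + 1L)
}

#' Histogram of box centers
#'
#' Normalized frequency of box centers \code{(cx, cy)} over a
#' \code{bins x bins} grid; rows index \code{cy} (top to bottom), columns
#' \code{cx}. Bins are half-open \code{[l, u)} with the last bin closed, so
#' values exactly on an interior edge fall in the upper bin. Reveals the
#' central placement bias of field-photographed datasets.
#'
#' @param ds a \linkS4class{DetectionDataset}.
#' @param bins grid resolution per axis.
#' @return matrix summing to 1, or a \code{0 x 0} matrix if the dataset has
#'   no boxes (the empty sentinel).
#' @export
centerHistogram <- function(ds, bins = 10L) {
    stopifnot(bins >= 1L)
    all <- do.call(rbind, ds@annotations)
    if (is.null(all) || nrow(all) == 0L)
        return(matrix(numeric(), 0L, 0L))
    m <- matrix(0, bins, bins)
    ri <- .binIndex(all$cy, bins)
    ci <- .binIndex(all$cx, bins)
    for (k in seq_len(nrow(all)))
        m[ri[k], ci[k]] <- m[ri[k], ci[k]] + 1
    m / sum(m)
}

#' Histogram of box scales
#'
#' Normalized frequency of \eqn{\sqrt{wh}} (normalized box side-equivalent)
#' over \code{bins} half-open bins on (0, 1]. Narrow occupancy indicates the
#' dataset covers only a thin slice of object scales.
#'
#' @inheritParams centerHistogram
#' @return numeric vector summing to 1, or \code{numeric(0)} if no boxes.
#' @export
scaleHistogram <- function(ds, bins = 10L) {
    stopifnot(bins >= 1L)
    all <- do.call(rbind, ds@annotations)
    if (is.null(all) || nrow(all) == 0L)
        return(numeric())
    s <- sqrt(all$w * all$h)
    v <- tabulate(.binIndex(s, bins), nbins = bins)
    v / sum(v)
}

#' Full distribution report for a dataset
#'
#' Bundles every diagnostic: imbalance ratio, log dispersion,
#' effective-category coverage and effective-sample proportion at threshold
#' \code{n0}, and the center/scale histograms.
#'
#' @param ds a \linkS4class{DetectionDataset}.
#' @param n0 effectiveness threshold.
#' @param bins histogram resolution.
#' @return a \linkS4class{DistributionReport}.
#' @export
distributionReport <- function(ds, n0 = 200L, bins = 10L) {
    d <- classDistribution(ds)
    cov <- effectiveCoverage(d, n0)
    new("DistributionReport", distribution = d,
        imbalanceRatio = imbalanceRatio(d),
        logDispersion = logDispersion(d),
        n0 = as.integer(n0), effectiveCount = cov$count,
        effectiveFraction = cov$fraction,
        effectiveSampleFraction = effectiveSampleProportion(d, n0),
        centerHistogram = centerHistogram(ds, bins),
        scaleHistogram = scaleHistogram(ds, bins))
}

setMethod("show", "DistributionReport", function(object) {
    cat("DistributionReport\n")
    cat(sprintf("  imbalance ratio          : %.2f\n", object@imbalanceRatio))
    cat(sprintf("  log dispersion           : %.3f\n", object@logDispersion))
    cat(sprintf("  effective classes (N0=%d): %d/%d (%.1f%%)\n", object@n0,
                object@effectiveCount, length(object@distribution@counts),
                100 * object@effectiveFraction))
    cat(sprintf("  effective-sample fraction: %.1f%%\n",
                100 * object@effectiveSampleFraction))
})

#' Compare two distribution reports
#'
#' Per-statistic deltas (after minus before) plus flags for the two changes
#' augmentation aims at: a decreased imbalance ratio and increased
#' effective-category coverage.
#'
#' @param before,after \linkS4class{DistributionReport}s over the same class
#'   table.
#' @return list with \code{deltaImbalanceRatio}, \code{deltaLogDispersion},
#'   \code{deltaEffectiveCount}, \code{deltaEffectiveFraction},
#'   \code{deltaEffectiveSampleFraction}, \code{irDecreased},
#'   \code{coverageIncreased}.
#' @export
compareReports <- function(before, after) {
    stopifnot(is(before, "DistributionReport"), is(after, "DistributionReport"))
    if (!identical(before@distribution@classNames,
                   after@distribution@classNames))
        stop("reports cover different class tables")
    list(deltaImbalanceRatio = after@imbalanceRatio - before@imbalanceRatio,
         deltaLogDispersion = after@logDispersion - before@logDispersion,
         deltaEffectiveCount = after@effectiveCount - before@effectiveCount,
         deltaEffectiveFraction = after@effectiveFraction -
             before@effectiveFraction,
         deltaEffectiveSampleFraction = after@effectiveSampleFraction -
             before@effectiveSampleFraction,
         irDecreased = after@imbalanceRatio < before@imbalanceRatio,
         coverageIncreased = after@effectiveCount > before@effectiveCount)
}

#' Serialize a report to JSON / markdown
#'
#' @param report a \linkS4class{DistributionReport}.
#' @return \code{reportToList}: plain list (JSON-ready);
#'   \code{reportToMarkdown}: character vector of markdown lines.
#' @export
reportToList <- function(report) {
    list(counts = as.list(counts(report@distribution)),
         imbalance_ratio = report@imbalanceRatio,
         log_dispersion = report@logDispersion,
         n0 = report@n0,
         effective_count = report@effectiveCount,
         effective_fraction = report@effectiveFraction,
         effective_sample_fraction = report@effectiveSampleFraction,
         center_histogram = report@centerHistogram,
         scale_histogram = report@scaleHistogram)
}

#' @rdname reportToList
#' @export
reportToMarkdown <- function(report) {
    c("| statistic | value |", "|---|---|",
      sprintf("| imbalance ratio | %.2f |", report@imbalanceRatio),
      sprintf("| log dispersion | %.3f |", report@logDispersion),
      sprintf("| effective classes (N0=%d) | %d/%d (%.1f%%) |", report@n0,
              report@effectiveCount, length(report@distribution@counts),
              100 * report@effectiveFraction),
      sprintf("| effective-sample fraction | %.1f%% |",
              100 * report@effectiveSampleFraction))
}
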