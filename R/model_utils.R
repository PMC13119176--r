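#' High-resolution gradient-weighted response map
#'
#' Computes \eqn{L = ReLU(\sum_k \partial y/\partial A_k \odot A_k)}: the
#' channel-summed element-wise product of feature maps and their gradients,
#' rectified. Unlike the pooled baseline, the spatial structure of the
#' gradients is kept, so the map preserves resolution at boundaries and for
#' small targets. Operates on user-supplied arrays; no network hooks.
#'
#' @param maps numeric \code{H x W x K} array of feature planes
#'   \eqn{A_k}.
#' @param grads same-shape array of gradients \eqn{\partial y / \partial
#'   A_k}.
#' @return non-negative \code{H x W} matrix.
#' @examples
#' m <- array(rnorm(32), c(4, 4, 2)); g <- array(rnorm(32), c(4, 4, 2))
#' range(hirescam(m, g))
#' @export
hirescam <- function(maps, grads) {
    maps <- .asStack(maps); grads <- .asStack(grads)
    if (!identical(dim(maps), dim(grads)))
        stop("maps and grads must have identical shapes")
    pmax(apply(maps * grads, c(1, 2), sum), 0)
}

#' Channel-pooled response-map baseline
#'
#' The classic pooled form: each channel is weighted by the spatial mean of
#' its gradient plane, \eqn{L = ReLU(\sum_k w_k A_k)} with \eqn{w_k =
#' mean(\partial y/\partial A_k)}. Coincides with \code{\link{hirescam}}
#' exactly when every gradient plane is spatially constant.
#'
#' @inheritParams hirescam
#' @return non-negative \code{H x W} matrix.
#' @export
gradcamBaseline <- function(maps, grads) {
    maps <- .asStack(maps); grads <- .asStack(grads)
    if (!identical(dim(maps), dim(grads)))
        stop("maps and grads must have identical shapes")
    w <- apply(grads, 3, mean)
    acc <- matrix(0, dim(maps)[1], dim(maps)[2])
    for (k in seq_len(dim(maps)[3]))
        acc <- acc + w[k] * maps[, , k]
    pmax(acc, 0)
}

.asStack <- function(x) {
    if (is.matrix(x))
        x <- array(x, c(dim(x), 1L))
    if (length(dim(x)) != 3L)
        stop("feature stack must be an H x W x K array")
    x
}

#' FLOPs estimate for parallel multi-scale convolution branches
#'
#' For an input feature map of size \eqn{C \times H \times W} and parallel
#' square kernels \eqn{k_i}, the added cost is
#' \eqn{\Delta FLOPs \approx \sum_i C^2 k_i^2 H W} (multiply-count
#' convention: one FLOP per multiply, no factor 2 for multiply-add).
#' Additive over the kernel list, linear in \eqn{HW}, quadratic in \eqn{C}.
#'
#' @param C channel count.
#' @param H,W spatial size.
#' @param kernels integer vector of kernel sizes \eqn{k_i}.
#' @return numeric FLOPs estimate.
#' @examples
#' emscpFlops(16, 8, 8, 3)         # 16^2 * 9 * 64 = 147456
#' emscpFlops(64, 40, 40, c(3, 5))
#' @export
emscpFlops <- function(C, H, W, kernels) {
    stopifnot(C > 0, H > 0, W > 0, all(kernels > 0))
    sum(as.numeric(C)^2 * as.numeric(kernels)^2 * as.numeric(H) *
        as.numeric(W))
}
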