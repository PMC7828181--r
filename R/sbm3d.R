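# R surface of the speckle-adapted BM3D filter.  The heavy lifting (block
# matching, the tight-frame undecimated wavelet, LLMMSE/Wiener shrinkage,
# aggregation) lives in src/sbm3d.cpp; these wrappers validate inputs,
# handle padding and expose each stage for direct use and testing.

#' Probabilistic patch distance for amplitude speckle
#'
#' The likelihood-based distance between two patches under the L-look
#' square-root-Gamma amplitude model, with an optional prior term:
#' \deqn{D = \sum_k (2L-1)\,\log\!\big(a_s(k)/a_t(k) + a_t(k)/a_s(k)\big)
#'   + \gamma\,\frac{(\hat x_s(k)-\hat x_t(k))^2}{\hat x_s(k)\,\hat x_t(k)}}
#' Amplitudes are clamped at \code{1e-6} before the log-ratio.  Identical
#' patches with \code{gamma = 0} attain the minimum \code{P (2L-1) log 2};
#' the distance is symmetric in its arguments.
#'
#' @param a_s,a_t numeric matrices (noisy amplitude patches), same shape.
#' @param prior_s,prior_t prior (first-pass denoised) patches; required when
#'   \code{gamma > 0}.
#' @param looks number of looks L.
#' @param gamma weight of the prior term, nonnegative.
#' @return a finite nonnegative scalar (for \code{looks >= 1/2}).
#' @export
patchDistance <- function(a_s, a_t, prior_s = NULL, prior_t = NULL,
                          looks = 4, gamma = 0) {
    assert_image(a_s, "a_s"); assert_image(a_t, "a_t")
    assert_same_shape(a_s, a_t)
    if (gamma < 0) stop("gamma must be nonnegative")
    if (gamma > 0) {
        if (is.null(prior_s) || is.null(prior_t))
            stop("prior patches are required when gamma > 0")
        assert_same_shape(a_s, prior_s, prior_t)
    }
    cpp_patch_distance(a_s, a_t, prior_s, prior_t, looks, gamma)
}

#' Group similar patches around a reference
#'
#' Evaluates \code{\link{patchDistance}} for every candidate patch whose
#' support lies in the search window centered on the reference (stride 1)
#' and keeps the \code{maxGroup} smallest distances; the reference is always
#' a member and distances are returned in nondecreasing order.
#'
#' @param img numeric matrix (noisy amplitudes).
#' @param ref \code{c(row, col)} of the reference patch's top-left corner
#'   (1-based); the patch must lie fully inside the image.
#' @param params a \code{\link{DenoiserParams}}.
#' @param prior optional prior image; required when \code{params@gamma > 0}
#'   (the second-pass distance).
#' @return list with \code{rows}, \code{cols} (1-based top-left corners) and
#'   \code{dist}, sorted by nondecreasing distance.
#' @export
blockMatch <- function(img, ref, params = DenoiserParams(), prior = NULL) {
    assert_image(img)
    validObject(params)
    b <- params@blockSize
    if (ref[1] < 1 || ref[2] < 1 || ref[1] + b - 1 > nrow(img) ||
        ref[2] + b - 1 > ncol(img))
        stop("reference patch must lie fully inside the image")
    gamma <- params@gamma
    if (gamma > 0 && is.null(prior))
        stop("prior image required when gamma > 0")
    res <- cpp_block_match(img, prior, as.integer(ref[1]) - 1L,
                           as.integer(ref[2]) - 1L, b, params@searchWindow,
                           params@maxGroup, params@looks, gamma)
    list(rows = res$rows + 1L, cols = res$cols + 1L, dist = res$dist)
}

# gather a K x B x B patch stack (array) at the given top-left corners
gather_stack <- function(img, rows, cols, b) {
    k <- length(rows)
    stack <- array(0, dim = c(k, b, b))
    for (i in seq_len(k))
        stack[i, , ] <- img[rows[i]:(rows[i] + b - 1), cols[i]:(cols[i] + b - 1)]
    stack
}

#' First-pass LLMMSE collaborative shrinkage
#'
#' Transforms a patch stack with the redundant 2-D wavelet per patch and the
#' orthonormal Haar transform along the stacking axis, then shrinks every
#' coefficient toward its subband-slice mean by the signal-to-total variance
#' ratio: \code{xhat = mu + sx2/(sx2 + sn2) (y - mu)} with
#' \code{sx2 = max(0, total - sn2)} and \code{sn2} the speckle-induced
#' coefficient noise variance (subband gain times
#' \code{speckleMultiplierVar(L)} times the squared mean group amplitude).
#' With \code{sn2 = 0} the operation is the identity up to transform
#' round-trip error.
#'
#' @param stack K x B x B array of patches, K a power of two.
#' @param params a \code{\link{DenoiserParams}}.
#' @param sigmaPix2 pixel-domain noise variance; by default derived from
#'   \code{params@looks} and the stack's mean amplitude.
#' @return denoised stack of the same shape.
#' @export
stage1Llmmse <- function(stack, params = DenoiserParams(),
                         sigmaPix2 = NULL) {
    stopifnot(is.array(stack), length(dim(stack)) == 3L)
    k <- dim(stack)[1]; b <- dim(stack)[2]
    stopifnot(dim(stack)[3] == b)
    if (any(!is.finite(stack))) stop("non-finite patch values")
    if (is.null(sigmaPix2))
        sigmaPix2 <- speckleMultiplierVar(params@looks) * mean(stack)^2
    flat <- aperm(stack, c(2, 3, 1))           # B x B x K, patch-major
    out <- cpp_stage1(as.numeric(flat), k, b, params@levels, sigmaPix2)
    aperm(array(out, dim = c(b, b, k)), c(3, 1, 2))
}

#' Second-pass empirical Wiener shrinkage
#'
#' In the same transform domain, every noisy coefficient \code{Z} is scaled
#' by \code{Xp^2 / (Xp^2 + V2)} where \code{Xp} is the first-pass prior
#' coefficient and \code{V2} the mean squared prior-noisy difference over
#' the coefficient's subband slice; a vanishing denominator passes zero.
#' With \code{V2 = 0} the stack is returned unchanged; a zero prior returns
#' zero.
#'
#' @param noisyStack,priorStack K x B x B arrays of matching shape, K a
#'   power of two.
#' @param params a \code{\link{DenoiserParams}}.
#' @return denoised stack of the same shape.
#' @export
stage2Wiener <- function(noisyStack, priorStack, params = DenoiserParams()) {
    stopifnot(is.array(noisyStack), length(dim(noisyStack)) == 3L)
    if (!identical(dim(noisyStack), dim(priorStack)))
        stop("stack shapes do not match")
    k <- dim(noisyStack)[1]; b <- dim(noisyStack)[2]
    zf <- as.numeric(aperm(noisyStack, c(2, 3, 1)))
    pf <- as.numeric(aperm(priorStack, c(2, 3, 1)))
    out <- cpp_stage2(zf, pf, k, b, params@levels)
    aperm(array(out, dim = c(b, b, k)), c(3, 1, 2))
}

#' Weighted aggregation of overlapping estimates
#'
#' The denoised value of a pixel is the weighted mean of every estimate it
#' received, \code{sum(w * x) / sum(w)}: the convention that preserves
#' constants for any positive weights.  Used pixelwise by the full filter
#' with inverse-residual-variance weights \code{w = 1/(1 + sigma2)}.
#'
#' @param estimates numeric vector of per-group estimates of one pixel (or a
#'   matrix with one row per group).
#' @param weights matching nonnegative weights.
#' @return the aggregated estimate (scalar, or vector for matrix input).
#' @examples
#' aggregateEstimates(c(2, 4), c(1, 3))  # 3.5
#' @export
aggregateEstimates <- function(estimates, weights) {
    if (is.matrix(estimates)) {
        stopifnot(nrow(estimates) == length(weights))
        return(colSums(estimates * weights) / sum(weights))
    }
    stopifnot(length(estimates) == length(weights), all(weights >= 0))
    if (sum(weights) <= 0) stop("pixel received no positive aggregation weight")
    sum(estimates * weights) / sum(weights)
}

#' Estimate the effective number of looks from an image
#'
#' Robust data-driven noise calibration: the noise standard deviation is
#' estimated from the median absolute deviation of horizontal
#' nearest-neighbor differences (scaled by \code{1/sqrt(2)}; MAD is
#' insensitive to the sparse vessel edges), divided by the mean intensity to
#' give the relative noise power, and inverted through
#' \code{\link{speckleMultiplierVar}} to an equivalent number of looks.
#' A nearly noise-free image maps to \code{maxLooks} (the filter then
#' approaches the identity).
#'
#' @param img numeric matrix.
#' @param fov optional logical matrix restricting the statistics.
#' @param minLooks,maxLooks clamp range of the estimate.
#' @return estimated looks, a scalar in \code{[minLooks, maxLooks]}.
#' @export
estimateLooks <- function(img, fov = NULL, minLooks = 0.5, maxLooks = 1e4) {
    assert_image(img)
    f <- if (is.null(fov)) matrix(TRUE, nrow(img), ncol(img)) else as_mask(fov)
    d <- (img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]) / sqrt(2)
    sel <- f[, -1, drop = FALSE] & f[, -ncol(img), drop = FALSE]
    sigma <- stats::mad(d[sel], center = 0)
    mu <- mean(img[f])
    if (sigma <= 0 || mu <= 0) return(maxLooks)
    rel2 <- (sigma / mu)^2
    if (rel2 >= speckleMultiplierVar(minLooks)) return(minLooks)
    if (rel2 <= speckleMultiplierVar(maxLooks)) return(maxLooks)
    stats::uniroot(function(L) speckleMultiplierVar(L) - rel2,
                   c(minLooks, maxLooks), tol = 1e-6)$root
}

#' Speckle-adapted BM3D denoising
#'
#' Full two-pass filter.  Pass 1 groups patches by the likelihood distance
#' (\code{gamma = 0}), shrinks each group by collaborative LLMMSE in the
#' redundant wavelet domain and aggregates overlapping estimates into a
#' prior image.  Pass 2 re-groups with the full distance (likelihood plus
#' prior term), applies the empirical Wiener filter against the pass-1
#' coefficients and aggregates again.  The image is padded symmetrically by
#' half the search window so border pixels get full groups.  The filter is
#' fully deterministic.
#'
#' @param img numeric matrix in [0,1].
#' @param params a \code{\link{DenoiserParams}}.
#' @param twoStage \code{FALSE} returns the first-pass (LLMMSE prior)
#'   aggregate.
#' @return denoised image, numeric matrix in [0,1], same shape as the input.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(size = 64L, polarity = "bright"))
#' noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 3L), clip = "unit")
#' den <- sbm3dDenoise(noisy, DenoiserParams(searchWindow = 15L, step = 4L))
#' @export
sbm3dDenoise <- function(img, params = DenoiserParams(), twoStage = TRUE) {
    assert_image(img)
    validObject(params)
    if (any(img < 0 | img > 1)) stop("img must lie in [0,1]")
    pad <- as.integer(ceiling(params@searchWindow / 2))
    pad <- min(pad, nrow(img), ncol(img))
    padded <- pad_symmetric(img, pad)
    out <- cpp_sbm3d(padded, params@blockSize, params@searchWindow,
                     params@step, params@maxGroup, params@looks,
                     params@gamma, params@levels,
                     speckleMultiplierVar(params@looks), twoStage)
    clamp01(out[(pad + 1):(pad + nrow(img)), (pad + 1):(pad + ncol(img)),
                drop = FALSE])
}
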