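# Vesselness detectors: Hessian eigenvalue filters (classic two-factor and
# eigenvalue-ratio variants) and the multiscale oriented second-derivative
# line detector.  Both operate on images where vessels are bright ridges
# (the preprocessing stage inverts dark vessels).

# FFT convolution with replicate boundary via EBImage
filt2 <- function(img, kernel) {
    res <- EBImage::filter2(EBImage::Image(img), kernel, boundary = "replicate")
    matrix(as.numeric(res), nrow(img), ncol(img))
}

# normalized discrete Gaussian and moment-corrected derivative kernels:
# the second-derivative kernel is forced to zero sum and exact second
# moment 2, the first-derivative kernel to exact first moment 1, so
# polynomial test images differentiate exactly.
gauss_1d <- function(s, r) {
    x <- (-r):r
    g <- exp(-x^2 / (2 * s^2))
    g / sum(g)
}
gderiv2_1d <- function(s, r) {
    x <- (-r):r
    k <- (x^2 - s^2) / s^4 * gauss_1d(s, r)
    k <- k - mean(k)
    k * (2 / sum(k * x^2))
}
gderiv1_1d <- function(s, r) {
    x <- (-r):r
    k <- (x / s^2) * gauss_1d(s, r)
    k / sum(k * x)
}

#' Scale-normalized Hessian and its eigenvalues
#'
#' Convolves the image with Gaussian second-derivative kernels at scale
#' \code{s}, multiplies by \code{s^2} (gamma-normalization) and returns the
#' per-pixel 2x2 Hessian entries together with its eigenvalues ordered by
#' magnitude (\code{abs(lambda1) <= abs(lambda2)}).
#'
#' @param img numeric matrix.
#' @param s Gaussian scale in pixels; at least 0.5 (smaller kernels are
#'   unresolvable on the pixel grid).
#' @return a \code{\linkS4class{HessianField}}.
#' @export
hessianEigen <- function(img, s) {
    assert_image(img)
    if (s < 0.5) stop("scale must be at least 0.5 px")
    r <- max(2L, as.integer(ceiling(4 * s)))
    r <- min(r, as.integer(floor((min(dim(img)) - 1) / 2)))
    gs <- gauss_1d(s, r); g2 <- gderiv2_1d(s, r); g1 <- gderiv1_1d(s, r)
    ixx <- s^2 * filt2(img, outer(gs, g2))
    iyy <- s^2 * filt2(img, outer(g2, gs))
    ixy <- s^2 * filt2(img, outer(g1, g1))
    half_tr <- (ixx + iyy) / 2
    disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
    e1 <- half_tr + disc
    e2 <- half_tr - disc
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    dim(l1) <- dim(l2) <- dim(img)
    new("HessianField", ixx = ixx, ixy = ixy, iyy = iyy,
        lambda1 = l1, lambda2 = l2, scale = s)
}

#' Classic two-factor Frangi vesselness
#'
#' \deqn{V_F = \big(1 - e^{-R_A^2/2\alpha^2}\big)\big(1 - e^{-S^2/2\kappa^2}\big)}
#' with the eigenvalue ratio \eqn{R_A = |\lambda_1|/|\lambda_2|} and the
#' structureness \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}; the response is
#' zeroed where the bright-ridge sign convention fails
#' (\eqn{\lambda_2 > 0}) and maximized over scales.  Kept in the two-factor
#' form; note its dependence on eigenvalue magnitudes is exactly what the
#' ratio-based variant (\code{\link{improvedFrangi}}, the pipeline detector)
#' removes.
#'
#' @param img numeric matrix (bright vessels).
#' @param params a \code{\link{FrangiParams}}.
#' @return vesselness map in [0,1].
#' @export
classicFrangi <- function(img, params = FrangiParams()) {
    assert_image(img)
    validObject(params)
    res <- matrix(0, nrow(img), ncol(img))
    for (s in params@scales) {
        hf <- hessianEigen(img, s)
        l1 <- hf@lambda1; l2 <- hf@lambda2
        str2 <- l1^2 + l2^2
        ra <- ifelse(abs(l2) > 0, abs(l1) / abs(l2), 0)
        kap <- params@kappa
        if (is.na(kap)) kap <- 0.5 * sqrt(max(str2))
        if (!is.finite(kap) || kap <= 1e-8) next   # no structure, only FFT dust
        v <- (1 - exp(-ra^2 / (2 * params@alpha^2))) *
            (1 - exp(-str2 / (2 * kap^2)))
        v[l2 > 0] <- 0
        v[str2 == 0] <- 0
        res <- pmax(res, v)
    }
    clamp01(res)
}

# ratio-based vesselness response given the (sign-flipped, bright-positive)
# large eigenvalue and its regularized companion
jerman_response <- function(l2, lrho) {
    out <- numeric(length(l2))
    pos <- l2 > 0 & lrho > 0
    plateau <- pos & l2 >= lrho / 2
    out[plateau] <- 1
    mid <- pos & !plateau
    out[mid] <- l2[mid]^2 * (lrho[mid] - l2[mid]) *
        (3 / (l2[mid] + lrho[mid]))^3
    out
}

#' Eigenvalue-ratio (improved) vesselness
#'
#' Ratio-based Hessian filter: with \eqn{\lambda_2} the larger-magnitude
#' eigenvalue sign-flipped so bright ridges give \eqn{\lambda_2 > 0}, and the
#' regularized \eqn{\lambda_\rho = \lambda_2} when
#' \eqn{\lambda_2 > \tau \max_x \lambda_2} (per scale, over the field of
#' view) and \eqn{\tau \max_x \lambda_2} otherwise, the response is 0 for
#' \eqn{\lambda_2 \le 0}, 1 on the plateau \eqn{\lambda_2 \ge \lambda_\rho/2},
#' and \eqn{\lambda_2^2(\lambda_\rho - \lambda_2)\,[3/(\lambda_2 +
#' \lambda_\rho)]^3} in between; maximized over scales.  Because the response
#' depends on an eigenvalue ratio rather than magnitudes, low-contrast thin
#' vessels are enhanced as strongly as thick ones.
#'
#' @param img numeric matrix (bright vessels).
#' @param params a \code{\link{FrangiParams}} (\code{tau} is the cutoff in
#'   [0, 1]).
#' @param fov optional logical matrix; the per-scale maximum of
#'   \eqn{\lambda_2} is taken over it.
#' @return vesselness map in [0,1].
#' @export
improvedFrangi <- function(img, params = FrangiParams(), fov = NULL) {
    assert_image(img)
    validObject(params)
    if (!is.null(fov)) fov <- as_mask(fov)
    res <- matrix(0, nrow(img), ncol(img))
    for (s in params@scales) {
        l2 <- -hessianEigen(img, s)@lambda2
        mx <- if (is.null(fov)) max(l2) else max(l2[fov])
        # the floor keeps convolution round-off on structureless images from
        # being promoted to a ridge by the ratio normalization
        if (!is.finite(mx) || mx <= 1e-8) next
        lrho <- ifelse(l2 > params@tau * mx, l2, params@tau * mx)
        v <- jerman_response(l2, lrho)
        dim(v) <- dim(img)
        res <- pmax(res, v)
    }
    clamp01(res)
}

#' Oriented anisotropic second-derivative line kernel
#'
#' Discrete sampling of the second \code{u}-derivative of an anisotropic
#' Gaussian,
#' \deqn{g_{uu}(u,v) = \frac{u^2 - \sigma_u^2}{2\pi\sigma_u^5\sigma_v}
#'   \exp\!\Big(-\frac{u^2}{2\sigma_u^2}-\frac{v^2}{2\sigma_v^2}\Big)}
#' rotated by \code{theta} via \code{u = x cos(theta) - y sin(theta)},
#' \code{v = x sin(theta) + y cos(theta)}, sampled on a support of
#' \code{±4 max(sigmaU, sigmaV)} pixels and mean-subtracted to enforce an
#' exactly zero sum.  Before the correction the center value is
#' \code{-1/(2 pi sigmaU^3 sigmaV)}.
#'
#' @param sigmaU,sigmaV Gaussian spreads along the rotated axes, pixels.
#' @param theta orientation in degrees.
#' @param radius optional support radius override, pixels.
#' @return a square numeric matrix with odd side and zero sum.
#' @export
lineKernel <- function(sigmaU, sigmaV, theta, radius = NULL) {
    stopifnot(sigmaU > 0, sigmaV > 0)
    r <- if (is.null(radius)) ceiling(4 * max(sigmaU, sigmaV)) else radius
    x <- matrix(rep((-r):r, each = 2 * r + 1), 2 * r + 1)   # column offset
    y <- matrix(rep((-r):r, times = 2 * r + 1), 2 * r + 1)  # row offset
    th <- theta * pi / 180
    u <- x * cos(th) - y * sin(th)
    v <- x * sin(th) + y * cos(th)
    g <- (u^2 - sigmaU^2) / (2 * pi * sigmaU^5 * sigmaV) *
        exp(-(u^2 / (2 * sigmaU^2) + v^2 / (2 * sigmaV^2)))
    g - mean(g)
}

#' The detector's kernel parameter grid
#'
#' One row per (width, elongation ratio, orientation) combination; with the
#' defaults, 2 widths x 7 ratios x 12 orientations = 168 kernels.
#'
#' @param params a \code{\link{LineDetectorParams}}.
#' @return data frame with columns \code{sigmaV}, \code{ratio},
#'   \code{sigmaU}, \code{theta}.
#' @export
lineKernelGrid <- function(params = LineDetectorParams()) {
    g <- expand.grid(theta = params@orientations, ratio = params@ratios,
                     sigmaV = params@sigmaV)
    data.frame(sigmaV = g$sigmaV, ratio = g$ratio,
               sigmaU = g$ratio * g$sigmaV, theta = g$theta)
}

#' Multiscale line detector response
#'
#' For every kernel of the parameter grid the image is convolved with the
#' oriented second-derivative kernel, negated (so a bright ridge aligned
#' with the kernel's \code{v} axis responds positively) and scale-normalized
#' by \code{sigmaU^alpha * sigmaV^beta}; the per-pixel response is the
#' maximum over the whole grid, clipped below at zero and normalized to
#' [0,1].
#'
#' @param img numeric matrix (bright vessels).
#' @param params a \code{\link{LineDetectorParams}}.
#' @return vesselness map in [0,1].
#' @export
multiscaleLineResponse <- function(img, params = LineDetectorParams()) {
    assert_image(img)
    validObject(params)
    grid <- lineKernelGrid(params)
    if (!nrow(grid)) stop("empty detector parameter grid")
    rmax <- as.integer(floor((min(dim(img)) - 1) / 2))
    res <- matrix(-Inf, nrow(img), ncol(img))
    for (i in seq_len(nrow(grid))) {
        su <- grid$sigmaU[i]; sv <- grid$sigmaV[i]
        r <- min(ceiling(4 * max(su, sv)), rmax)
        k <- lineKernel(su, sv, grid$theta[i], radius = r)
        resp <- su^params@alpha * sv^params@beta * (-filt2(img, k))
        res <- pmax(res, resp)
    }
    res <- pmax(res, 0)
    mx <- max(res)
    # same numerical floor: round-off on a constant image must not be
    # normalized up to full scale
    if (mx > 1e-8) res <- res / mx else res[] <- 0
    res
}
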