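# Postprocessing: Perona-Malik anisotropic diffusion of the vesselness map
# and ISODATA (Ridler-Calvard) binarization initialized by Otsu.

#' Perona-Malik anisotropic diffusion
#'
#' Iterative 4-neighbor diffusion in flux form,
#' \code{x <- x + dt * sum(g(grad) * grad)} over the N/S/E/W neighbor
#' differences, with the exponential (\code{exp(-(g/kappa)^2)}) or rational
#' (\code{1/(1+(g/kappa)^2)}) conduction function and reflective boundaries.
#' Gradients well below \code{kappa} are smoothed, gradients well above are
#' preserved, which evens a vessel's interior intensity without eroding its
#' edges.  The flux form conserves the global mean exactly; for input in
#' [0,1] every update is a convex combination so the output needs no
#' clipping beyond numerical safety.
#'
#' @param img numeric matrix in [0,1].
#' @param params a \code{\link{DiffusionParams}} (\code{dt} in (0, 0.25] for
#'   stability).
#' @return diffused image, numeric matrix in [0,1].
#' @export
anisotropicDiffusion <- function(img, params = DiffusionParams()) {
    assert_image(img)
    validObject(params)
    h <- nrow(img); w <- ncol(img)
    g <- if (params@conduction == "exponential") {
        function(d) exp(-(d / params@kappa)^2)
    } else {
        function(d) 1 / (1 + (d / params@kappa)^2)
    }
    x <- img
    for (it in seq_len(params@iterations)) {
        dn <- rbind(x[1, , drop = FALSE], x[-h, , drop = FALSE]) - x
        ds <- rbind(x[-1, , drop = FALSE], x[h, , drop = FALSE]) - x
        dw <- cbind(x[, 1, drop = FALSE], x[, -w, drop = FALSE]) - x
        de <- cbind(x[, -1, drop = FALSE], x[, w, drop = FALSE]) - x
        x <- x + params@dt *
            (g(dn) * dn + g(ds) * ds + g(dw) * dw + g(de) * de)
    }
    clamp01(x)
}

# Otsu threshold on histogram counts: the bin boundary maximizing
# between-class variance (first maximum on ties)
otsu_from_hist <- function(counts, mids) {
    nb <- length(counts)
    w <- counts / sum(counts)
    w0 <- cumsum(w)
    mu <- cumsum(w * mids)
    mu_t <- mu[nb]
    k <- seq_len(nb - 1)
    denom <- w0[k] * (1 - w0[k])
    sb <- ifelse(denom > 0, (mu_t * w0[k] - mu[k])^2 / denom, -Inf)
    which.max(sb)  # boundary index: classes are bins <= k vs > k
}

#' ISODATA (Ridler-Calvard) threshold
#'
#' Iterative global threshold on a 256-bin histogram of the masked values
#' over their occupied range [LO, UP]: starting from the Otsu level, the
#' threshold is repeatedly replaced by the midpoint of the two class means
#' it induces, \code{T <- (mu0 + mu1) / 2} with \code{mu0} the mean of bins
#' below \code{T} and \code{mu1} the mean of bins at or above it, until it
#' moves by less than half a bin width (or 100 iterations).  The converged
#' value is a fixed point of the class-mean midpoint map.
#'
#' @param values numeric matrix (e.g. a vesselness map).
#' @param mask optional logical matrix restricting the histogram.
#' @param nBins number of histogram bins.
#' @return the converged threshold (scalar), with the iteration count in
#'   attribute \code{"iterations"}.
#' @export
isodataThreshold <- function(values, mask = NULL, nBins = 256L) {
    assert_image(values, "values")
    v <- if (is.null(mask)) as.numeric(values) else values[as_mask(mask)]
    if (length(v) < 2L) stop("need at least two masked values")
    lo <- min(v); up <- max(v)
    if (up <= lo) stop("degenerate histogram: masked region is constant")
    bw <- (up - lo) / nBins
    idx <- pmin(nBins, floor((v - lo) / bw) + 1L)
    counts <- tabulate(idx, nBins)
    mids <- lo + (seq_len(nBins) - 0.5) * bw

    k0 <- otsu_from_hist(counts, mids)
    thr <- lo + k0 * bw
    iters <- 0L
    for (it in seq_len(100L)) {
        below <- mids < thr
        if (!any(counts[below]) || !any(counts[!below])) break
        mu0 <- sum(counts[below] * mids[below]) / sum(counts[below])
        mu1 <- sum(counts[!below] * mids[!below]) / sum(counts[!below])
        tnew <- (mu0 + mu1) / 2
        moved <- abs(tnew - thr)
        thr <- tnew
        iters <- it
        if (moved < bw / 2) break
    }
    structure(thr, iterations = iters)
}

#' Binarize a vesselness map
#'
#' A pixel is vessel iff its value is at or above the threshold and inside
#' the field of view (ties are assigned to the vessel class).  Monotone in
#' \code{T}: raising the threshold never adds vessel pixels.
#'
#' @param vmap numeric matrix.
#' @param threshold finite scalar.
#' @param fov optional logical matrix.
#' @return logical matrix.
#' @export
binarize <- function(vmap, threshold, fov = NULL) {
    assert_image(vmap, "vmap")
    if (!is.finite(threshold)) stop("threshold must be finite")
    out <- vmap >= threshold
    if (!is.null(fov)) out <- out & as_mask(fov)
    out
}
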