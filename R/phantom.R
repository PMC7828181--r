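# Synthetic fundus phantom generator: branching vessels with Gaussian
# cross-sections inside a circular field of view, plus L-look amplitude
# speckle.  Every downstream stage is validated against these phantoms.

# exact point-to-segment distance, vectorized over pixels
seg_dist <- function(px, py, ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
    t <- clamp01(((px - ax) * vx + (py - ay) * vy) / len2)
    sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}

# centerline polyline of one vessel descriptor (quadratic Bezier if a
# control point is present, otherwise the straight segment itself)
vessel_polyline <- function(v) {
    if (is.null(v$ctrl)) {
        rbind(v$from, v$to)
    } else {
        chord <- sqrt(sum((v$to - v$from)^2)) +
            sqrt(sum((v$ctrl - v$from)^2)) + sqrt(sum((v$to - v$ctrl)^2))
        n <- max(16L, ceiling(2 * chord))
        t <- seq(0, 1, length.out = n)
        cbind((1 - t)^2 * v$from[1] + 2 * (1 - t) * t * v$ctrl[1] + t^2 * v$to[1],
              (1 - t)^2 * v$from[2] + 2 * (1 - t) * t * v$ctrl[2] + t^2 * v$to[2])
    }
}

# minimum distance from every pixel of a window to a polyline
polyline_dist <- function(px, py, pts) {
    d <- rep(Inf, length(px))
    for (i in seq_len(nrow(pts) - 1L)) {
        d <- pmin(d, seg_dist(px, py, pts[i, 1], pts[i, 2],
                              pts[i + 1, 1], pts[i + 1, 2]))
    }
    d
}

#' Render a synthetic fundus phantom
#'
#' Draws every vessel of the spec as a Gaussian-profile ridge over a flat
#' background: at perpendicular distance \code{d} from a centerline of
#' amplitude \code{A} and cross-section \code{sigma} the intensity is
#' \code{background + A * exp(-d^2 / (2 sigma^2))} (overlaps take the
#' maximum contribution, so the centerline value is exact).  Dark-polarity
#' phantoms are the inverted rendering.  Pixels outside the centered
#' field-of-view disc are set to zero (the dark rim of a fundus photograph),
#' and the ground-truth mask is the set of pixels within \code{2 sigma} of a
#' centerline intersected with the FOV.  The output is a deterministic
#' function of the spec.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @return list with components \code{clean} (numeric matrix in [0,1]),
#'   \code{truth} and \code{fov} (logical matrices).
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(size = 96L))
#' range(ph$clean)
#' @export
generatePhantom <- function(spec) {
    validObject(spec)
    w <- spec@width; h <- spec@height
    ridge <- matrix(0, h, w)
    support <- matrix(FALSE, h, w)

    for (v in spec@vessels) {
        pts <- vessel_polyline(v)
        r <- ceiling(5 * v$sigma) + 1L
        c0 <- max(1L, floor(min(pts[, 1])) - r)
        c1 <- min(w, ceiling(max(pts[, 1])) + r)
        r0 <- max(1L, floor(min(pts[, 2])) - r)
        r1 <- min(h, ceiling(max(pts[, 2])) + r)
        if (c0 > c1 || r0 > r1) next
        cols <- c0:c1; rows <- r0:r1
        px <- rep(cols, each = length(rows))
        py <- rep(rows, times = length(cols))
        d <- polyline_dist(px, py, pts)
        contrib <- v$amp * exp(-d^2 / (2 * v$sigma^2))
        idx <- cbind(py, px)
        ridge[idx] <- pmax(ridge[idx], contrib)
        support[idx] <- support[idx] | (d <= 2 * v$sigma)
    }

    clean <- spec@backgroundLevel + ridge
    if (any(clean > 1))
        warning("vessel amplitudes exceed the intensity range; clipping to [0,1]")
    clean <- clamp01(clean)
    if (spec@polarity == "dark") clean <- 1 - clean

    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    rad <- spec@fovRadiusFraction * min(w, h) / 2
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(rep(seq_len(h), times = w), h, w)
    fov <- (X - cx)^2 + (Y - cy)^2 <= rad^2

    clean[!fov] <- 0
    list(clean = clean, truth = support & fov, fov = fov)
}

#' Mean of the unnormalized L-look amplitude speckle multiplier
#'
#' If \code{u0^2 ~ Gamma(shape = L, scale = 1/L)} then
#' \code{E[u0] = Gamma(L + 1/2) / (Gamma(L) sqrt(L))}; dividing by it makes
#' the multiplier unit-mean.
#'
#' @param looks number of looks L, positive.
#' @return the mean, a scalar in (0, 1].
#' @export
speckleMultiplierMean <- function(looks) {
    stopifnot(looks > 0)
    exp(lgamma(looks + 0.5) - lgamma(looks)) / sqrt(looks)
}

#' Variance of the unit-mean L-look amplitude speckle multiplier
#'
#' Since \code{E[u0^2] = 1}, the unit-mean multiplier
#' \code{u = u0 / E[u0]} has variance \code{1 / E[u0]^2 - 1}; this is the
#' per-pixel relative noise power the denoiser calibrates against.
#'
#' @inheritParams speckleMultiplierMean
#' @return the variance, a positive scalar decreasing in \code{looks}.
#' @export
speckleMultiplierVar <- function(looks) {
    m <- speckleMultiplierMean(looks)
    1 / m^2 - 1
}

#' Apply multiplicative speckle (and optional additive noise)
#'
#' Each pixel is multiplied by an independent unit-mean draw \code{u} with
#' \code{u^2 ~ Gamma(shape = L, scale = 1/L)} rescaled by
#' \code{\link{speckleMultiplierMean}}, so the expected noisy image equals
#' the clean image.  Optional additive Gaussian noise follows.  The result
#' is clipped below at zero; \code{clip = "unit"} additionally clips at one
#' for storage in [0,1].
#'
#' @param clean numeric matrix in [0,1].
#' @param noise a \code{\link{NoiseSpec}}.
#' @param clip \code{"none"} (default) or \code{"unit"}.
#' @return noisy image matrix; deterministic given the spec's seed.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(size = 64L))
#' noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 7L))
#' @export
applySpeckle <- function(clean, noise, clip = c("none", "unit")) {
    clip <- match.arg(clip)
    assert_image(clean, "clean")
    validObject(noise)
    if (any(clean < 0 | clean > 1)) stop("clean image must lie in [0,1]")
    n <- length(clean)
    L <- noise@looks
    out <- with_seed(noise@seed, {
        u <- sqrt(rgamma(n, shape = L, rate = L)) / speckleMultiplierMean(L)
        res <- clean * u
        if (noise@additiveSigma > 0)
            res <- res + rnorm(n, 0, noise@additiveSigma)
        res
    })
    out <- pmax(out, 0)
    if (clip == "unit") out <- pmin(out, 1)
    matrix(out, nrow(clean), ncol(clean))
}

#' Default phantom layout
#'
#' A fixed vascular layout emulating the geometry a segmentation pipeline
#' must cope with: two thick arcades, medium branches and several thin
#' vessels, spanning the field of view, with widths (sigma 3.2 / 2.0 / 1.1
#' px) and centerline contrasts (0.40 / 0.32 / 0.25) graded from thick to
#' thin the way fundus vessels are.  The layout scales with the requested
#' size; vessels are dark by default, as in real fundus photographs.
#'
#' @param size image side in pixels.
#' @param polarity \code{"dark"} (default) or \code{"bright"}.
#' @param backgroundLevel background of the bright rendering.
#' @param seed stored in the spec (see \code{\link{PhantomSpec}}).
#' @return a \code{\link{PhantomSpec}}.
#' @export
defaultPhantomSpec <- function(size = 256L, polarity = "dark",
                               backgroundLevel = 0.4, seed = 1L) {
    s <- as.numeric(size) / 256
    v <- function(from, to, amp, sigma, ctrl = NULL) {
        out <- list(from = from * s, to = to * s, amp = amp, sigma = sigma * s)
        if (!is.null(ctrl)) out$ctrl <- ctrl * s
        out
    }
    vessels <- list(
        # thick arcades
        v(c(30, 128), c(235, 60),  0.40, 3.2, ctrl = c(130, 20)),
        v(c(30, 128), c(235, 200), 0.40, 3.2, ctrl = c(130, 245)),
        # medium branches
        v(c(120, 52),  c(210, 120), 0.32, 2.0),
        v(c(128, 222), c(215, 150), 0.32, 2.0),
        v(c(55, 105),  c(120, 190), 0.32, 2.0, ctrl = c(60, 160)),
        # thin vessels
        v(c(150, 75),  c(150, 185), 0.25, 1.1),
        v(c(90, 70),   c(60, 180),  0.25, 1.1),
        v(c(180, 95),  c(235, 130), 0.25, 1.1),
        v(c(110, 130), c(185, 95),  0.25, 1.1)
    )
    PhantomSpec(width = size, height = size,
                backgroundLevel = backgroundLevel, vessels = vessels,
                polarity = polarity, seed = seed)
}

#' Random branching vessel layout
#'
#' Grows a small random vascular tree (trunks that fork into thinner
#' children, widths and contrasts shrinking with depth) for property-style
#' tests that need layout diversity.  Deterministic given the seed.
#'
#' @param seed integer RNG seed.
#' @param size image side in pixels.
#' @param polarity,backgroundLevel passed to \code{\link{PhantomSpec}}.
#' @return a \code{\link{PhantomSpec}} with \code{seed} recorded.
#' @export
randomVesselTree <- function(seed, size = 256L, polarity = "dark",
                             backgroundLevel = 0.4) {
    vessels <- with_seed(seed, {
        out <- list()
        grow <- function(x, y, angle, len, sigma, amp, depth) {
            if (depth > 3 || len < 12 || sigma < 0.8) return()
            x2 <- x + len * cos(angle); y2 <- y + len * sin(angle)
            mid <- c((x + x2) / 2, (y + y2) / 2) +
                stats::runif(2, -0.15, 0.15) * len
            out[[length(out) + 1L]] <<- list(
                from = c(x, y), to = c(x2, y2), ctrl = mid,
                amp = amp, sigma = sigma)
            nkids <- sample(1:2, 1)
            for (k in seq_len(nkids)) {
                grow(x2, y2, angle + stats::runif(1, -0.9, 0.9),
                     len * stats::runif(1, 0.55, 0.8), sigma * 0.7,
                     amp * 0.85, depth + 1)
            }
        }
        ntrunk <- 3L
        for (i in seq_len(ntrunk)) {
            a0 <- 2 * pi * (i - 0.5) / ntrunk + stats::runif(1, -0.3, 0.3)
            grow(size / 2 + 0.12 * size * cos(a0),
                 size / 2 + 0.12 * size * sin(a0),
                 a0, 0.28 * size, 3.0 * size / 256, 0.4, 1)
        }
        out
    })
    PhantomSpec(width = size, height = size,
                backgroundLevel = backgroundLevel, vessels = vessels,
                polarity = polarity, seed = seed)
}
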