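# Preprocessing: vessel-contrast channel extraction, FOV-aware CLAHE and
# field-of-view estimation.

#' Extract the vessel-contrast channel
#'
#' Returns the green channel of a color fundus image (the channel with the
#' strongest vessel contrast), inverted when \code{polarity = "dark"} so that
#' vessels become bright ridges for the detectors.  Single-channel input is
#' passed through (and inverted for dark polarity).
#'
#' @param img numeric matrix, or H x W x 3 array in [0,1].
#' @param polarity \code{"dark"} for real fundus images (vessels darker than
#'   background), \code{"bright"} to pass the channel through unchanged.
#' @return numeric matrix in [0,1].
#' @examples
#' rgb <- array(c(0.2, 0.7, 0.1), dim = c(1, 1, 3))
#' extractVesselChannel(rgb, "dark")  # 1 - 0.7
#' @export
extractVesselChannel <- function(img, polarity = c("dark", "bright")) {
    polarity <- match.arg(polarity)
    if (is.matrix(img)) {
        ch <- img
    } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
        ch <- matrix(img[, , 2], dim(img)[1], dim(img)[2])
    } else {
        stop("expected a matrix or an H x W x 3 array")
    }
    if (polarity == "dark") 1 - ch else ch
}

# mapping lookup tables per tile: clipped-histogram CDF; degenerate tiles
# (one occupied bin, or no in-mask pixels) get the identity mapping so a
# constant region is a fixed point.
clahe_tile_maps <- function(img, fov, gr, gc, nb, clip) {
    h <- nrow(img); w <- ncol(img)
    tile_h <- h / gr; tile_w <- w / gc
    tr <- pmin(gr, floor((row(img) - 0.5) / tile_h) + 1L)
    tc <- pmin(gc, floor((col(img) - 0.5) / tile_w) + 1L)
    bin <- pmin(nb, floor(img * nb) + 1L)
    centers <- (seq_len(nb) - 0.5) / nb
    maps <- array(rep(centers, each = gr * gc), dim = c(gr, gc, nb))
    for (i in seq_len(gr)) {
        for (j in seq_len(gc)) {
            sel <- tr == i & tc == j & fov
            if (!any(sel)) next
            counts <- tabulate(bin[sel], nb)
            if (sum(counts > 0) < 2L) next
            cl <- clip * sum(counts) / nb
            excess <- sum(pmax(counts - cl, 0))
            counts <- pmin(counts, cl) + excess / nb
            maps[i, j, ] <- cumsum(counts) / sum(counts)
        }
    }
    list(maps = maps, bin = bin)
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE with bilinear interpolation between tile mappings.  Histograms are
#' computed over field-of-view pixels only when a mask is given, so the dark
#' rim of a fundus photograph cannot dominate the tile statistics at the
#' border.  Tiles whose (masked) histogram is concentrated in a single bin
#' keep the identity mapping, which makes constant images fixed points.
#'
#' @param img numeric matrix in [0,1].
#' @param fov optional logical matrix; pixels outside it are excluded from
#'   the histogram statistics (but still remapped).
#' @param params a \code{\link{ClaheParams}}.
#' @return enhanced image, numeric matrix in [0,1].
#' @export
claheEnhance <- function(img, fov = NULL, params = ClaheParams()) {
    assert_image(img)
    validObject(params)
    if (any(img < 0 | img > 1)) stop("img must lie in [0,1]")
    h <- nrow(img); w <- ncol(img)
    if (is.null(fov)) fov <- matrix(TRUE, h, w)
    fov <- as_mask(fov)
    assert_same_shape(img, fov)
    gr <- params@tiles[1]; gc <- params@tiles[2]
    if (gr > h || gc > w) {
        warning("tile grid finer than the image; falling back to global equalization")
        gr <- 1L; gc <- 1L
    }
    nb <- params@nBins
    tm <- clahe_tile_maps(img, fov, gr, gc, nb, params@clipLimit)

    # bilinear interpolation between the four surrounding tile mappings
    tile_h <- h / gr; tile_w <- w / gc
    gy <- (row(img) - 0.5) / tile_h + 0.5
    gx <- (col(img) - 0.5) / tile_w + 0.5
    y0 <- floor(gy); x0 <- floor(gx)
    wy <- gy - y0; wx <- gx - x0
    y0c <- pmin(pmax(y0, 1L), gr); y1c <- pmin(y0 + 1L, gr)
    x0c <- pmin(pmax(x0, 1L), gc); x1c <- pmin(x0 + 1L, gc)
    b <- tm$bin
    m00 <- tm$maps[cbind(c(y0c), c(x0c), c(b))]
    m01 <- tm$maps[cbind(c(y0c), c(x1c), c(b))]
    m10 <- tm$maps[cbind(c(y1c), c(x0c), c(b))]
    m11 <- tm$maps[cbind(c(y1c), c(x1c), c(b))]
    out <- (1 - wy) * ((1 - wx) * m00 + wx * m01) +
        wy * ((1 - wx) * m10 + wx * m11)
    matrix(clamp01(out), h, w)
}

#' Estimate the field-of-view mask
#'
#' Thresholds the image (red channel of a color input) at a fraction of its
#' Otsu level, keeps the largest connected component, closes it
#' morphologically and fills interior holes.  The result is a single
#' hole-free component.
#'
#' @param img numeric matrix or H x W x 3 array in [0,1].
#' @param thresholdFraction multiple of the Otsu level used as threshold.
#' @param closeRadius radius (pixels) of the disc used for morphological
#'   closing.
#' @return logical matrix.
#' @export
estimateFov <- function(img, thresholdFraction = 0.5, closeRadius = 5L) {
    if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
    assert_image(img)
    if (any(img < 0 | img > 1)) stop("img must lie in [0,1]")
    thr <- thresholdFraction * EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    mask <- img > thr
    if (!any(mask)) stop("empty foreground after thresholding")
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
    brush <- EBImage::makeBrush(2L * as.integer(closeRadius) + 1L, "disc")
    mask <- EBImage::closing(mask, brush)
    mask <- EBImage::fillHull(mask)
    out <- as.matrix(mask) > 0
    dim(out) <- dim(img)
    out
}
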