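# Channel extraction, CLAHE, FOV estimation

test_that("vessel channel extraction picks green and handles polarity", {
    rgb <- array(0, dim = c(1, 1, 3))
    rgb[1, 1, ] <- c(0.2, 0.7, 0.1)
    expect_equal(extractVesselChannel(rgb, "dark")[1, 1], 0.3)
    expect_equal(extractVesselChannel(rgb, "bright")[1, 1], 0.7)
    g <- matrix(runif(16), 4)
    expect_equal(extractVesselChannel(g, "bright"), g)      # passthrough
    expect_equal(1 - extractVesselChannel(g, "dark"), g)    # involution
    expect_error(extractVesselChannel(array(0, c(2, 2, 4))), "3")
})

test_that("CLAHE fixes constant images and respects the intensity range", {
    cst <- matrix(0.37, 40, 40)
    out <- claheEnhance(cst, params = ClaheParams(tiles = c(4L, 4L)))
    expect_lt(max(abs(out - out[1, 1])), 1e-12)   # still constant
    out2 <- claheEnhance(out, params = ClaheParams(tiles = c(4L, 4L)))
    expect_equal(out2, out)                       # idempotent on constants
    set.seed(1)
    rnd <- matrix(runif(64 * 64), 64)
    enh <- claheEnhance(rnd)
    expect_gte(min(enh), 0)
    expect_lte(max(enh), 1)
})

test_that("CLAHE increases the separation of a low-contrast two-class image", {
    set.seed(2)
    cls <- matrix(sample(c(0L, 1L), 64 * 64, replace = TRUE), 64)
    img <- ifelse(cls == 0, 0.45, 0.55)
    enh <- claheEnhance(img, params = ClaheParams())
    gap_before <- abs(mean(img[cls == 1]) - mean(img[cls == 0]))
    gap_after <- abs(mean(enh[cls == 1]) - mean(enh[cls == 0]))
    expect_gt(gap_after, gap_before)
})

test_that("CLAHE falls back to global equalization for oversized tile grids", {
    img <- matrix(runif(36), 6)
    expect_warning(out <- claheEnhance(img, params = ClaheParams(tiles = c(10L, 10L))),
                   "global")
    expect_equal(dim(out), dim(img))
})

test_that("FOV estimation recovers a bright disc and rejects empty images", {
    n <- 256
    X <- matrix(rep(1:n, each = n), n); Y <- matrix(rep(1:n, n), n)
    disc <- (X - 128)^2 + (Y - 128)^2 <= 100^2
    img <- ifelse(disc, 0.7, 0.02)
    est <- estimateFov(img)
    iou <- sum(est & disc) / sum(est | disc)
    expect_gt(iou, 0.95)
    # single connected component, no interior holes
    lab <- EBImage::bwlabel(est)
    expect_equal(max(lab), 1)
    filled <- EBImage::fillHull(est) > 0
    expect_equal(sum(filled), sum(est))
    expect_error(estimateFov(matrix(0, 32, 32)), "foreground")
})
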