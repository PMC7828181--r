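# Anisotropic diffusion, ISODATA thresholding, binarization

test_that("diffusion fixes constants and conserves the global mean", {
    cst <- matrix(0.6, 32, 32)
    out <- anisotropicDiffusion(cst, DiffusionParams(iterations = 20L))
    expect_equal(out, cst)
    set.seed(12)
    img <- matrix(runif(40 * 40), 40)
    out <- anisotropicDiffusion(img, DiffusionParams(iterations = 50L))
    expect_lt(abs(mean(out) - mean(img)), 1e-6)
    expect_error(DiffusionParams(dt = 0.3), "dt")
})

test_that("diffusion denoises flat regions while keeping the step edge", {
    set.seed(13)
    n <- 64
    step_edge <- matrix(rep(c(rep(0.2, 32), rep(0.8, 32)), each = n), n)
    noisy <- step_edge + matrix(rnorm(n * n, 0, 0.02), n)
    out <- anisotropicDiffusion(noisy, DiffusionParams(iterations = 10L))
    tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
    expect_lt(tv(out), tv(noisy))
    # edge magnitude across the boundary survives
    edge_before <- mean(noisy[, 33] - noisy[, 32])
    edge_after <- mean(out[, 33] - out[, 32])
    expect_gte(edge_after, 0.5 * edge_before)
    # flat-region variance collapses
    expect_lte(var(as.numeric(out[10:50, 5:25])),
               0.2 * var(as.numeric(noisy[10:50, 5:25])))
})

test_that("ISODATA converges to the midpoint of two delta masses", {
    v <- matrix(c(rep(0.2, 600), rep(0.8, 400)), 40)
    thr <- isodataThreshold(v)
    expect_equal(as.numeric(thr), 0.5, tolerance = (0.8 - 0.2) / 256)
    expect_error(isodataThreshold(matrix(0.5, 10, 10)), "degenerate")
})

test_that("ISODATA is a fixed point of the class-mean midpoint map", {
    set.seed(14)
    for (i in 1:20) {
        v <- matrix(c(rnorm(400, 0.3, 0.08), rnorm(300, 0.7, 0.1)), 70)
        v <- pmin(pmax(v, 0), 1)
        thr <- as.numeric(isodataThreshold(v))
        lo <- min(v); up <- max(v); bw <- (up - lo) / 256
        idx <- pmin(256, floor((v - lo) / bw) + 1)
        counts <- tabulate(idx, 256)
        mids <- lo + (seq_len(256) - 0.5) * bw
        mu0 <- sum(counts[mids < thr] * mids[mids < thr]) /
            sum(counts[mids < thr])
        mu1 <- sum(counts[mids >= thr] * mids[mids >= thr]) /
            sum(counts[mids >= thr])
        expect_lt(abs(thr - (mu0 + mu1) / 2), bw / 2)
    }
})

test_that("ISODATA commutes with affine intensity rescaling", {
    set.seed(15)
    v <- matrix(pmin(pmax(c(rnorm(500, 0.3, 0.05), rnorm(500, 0.75, 0.08)),
                          0), 1), 50)
    t1 <- as.numeric(isodataThreshold(v))
    a <- 0.4; b <- 0.17
    t2 <- as.numeric(isodataThreshold(a * v + b))
    bw <- a * (max(v) - min(v)) / 256
    expect_lt(abs(t2 - (a * t1 + b)), bw)
})

test_that("binarization is a monotone threshold restricted to the FOV", {
    vm <- matrix(c(0.1, 0.9, 0.1, 0.1, 0.8, 0.1, 0.1, 0.7, 0.1), 3,
                 byrow = TRUE)
    full <- matrix(TRUE, 3, 3)
    out <- binarize(vm, 0.5, full)
    expect_equal(sum(out), 3L)
    expect_true(all(out[, 2]))
    expect_equal(binarize(vm, 0, full), full)      # everything passes at 0
    expect_false(any(binarize(vm, 0.95, full)))    # nothing above the max
    set.seed(16)
    v <- matrix(runif(100), 10)
    fov <- matrix(sample(c(TRUE, FALSE), 100, TRUE), 10)
    m1 <- binarize(v, 0.3, fov)
    m2 <- binarize(v, 0.6, fov)
    expect_true(all(m1[m2]))                       # raising T never adds
    expect_false(any(m1[!fov]))
    expect_error(binarize(v, Inf), "finite")
})
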