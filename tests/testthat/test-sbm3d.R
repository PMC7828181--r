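# S-BM3D building blocks (the acceptance file holds the exhaustive oracles;
# these are the structural unit tests)

test_that("patch distance is symmetric and validates its inputs", {
    set.seed(3)
    for (i in 1:50) {
        a <- matrix(runif(16, 0.05, 1), 4)
        b <- matrix(runif(16, 0.05, 1), 4)
        p <- matrix(runif(16, 0.05, 1), 4)
        q <- matrix(runif(16, 0.05, 1), 4)
        expect_equal(patchDistance(a, b, looks = 3), patchDistance(b, a, looks = 3))
        expect_equal(patchDistance(a, b, p, q, looks = 3, gamma = 2),
                     patchDistance(b, a, q, p, looks = 3, gamma = 2))
    }
    expect_error(patchDistance(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
    expect_error(patchDistance(matrix(1, 2, 2), matrix(1, 2, 2), gamma = 1),
                 "prior")
})

test_that("the reference patch always belongs to its own group", {
    set.seed(4)
    img <- matrix(runif(32 * 32, 0.1, 1), 32)
    p <- DenoiserParams(blockSize = 6L, searchWindow = 21L, maxGroup = 8L,
                        gamma = 0)
    for (ref in list(c(5L, 5L), c(14L, 20L), c(27L, 3L))) {
        g <- blockMatch(img, ref, p)
        expect_true(any(g$rows == ref[1] & g$cols == ref[2]))
        expect_lte(length(g$rows), 8L)
        expect_true(!is.unsorted(g$dist))
    }
})

test_that("planted copies of a distinctive patch are all recovered", {
    set.seed(5)
    img <- matrix(runif(32 * 32, 0.4, 0.6), 32)
    stamp <- matrix(runif(36, 0.05, 0.15), 6)   # much darker than background
    locs <- list(c(8L, 8L), c(8L, 20L), c(16L, 12L))
    for (l in locs) img[l[1]:(l[1] + 5), l[2]:(l[2] + 5)] <- stamp
    g <- blockMatch(img, locs[[1]], DenoiserParams(blockSize = 6L,
                                                   searchWindow = 31L,
                                                   maxGroup = 4L, gamma = 0))
    for (l in locs)
        expect_true(any(g$rows == l[1] & g$cols == l[2]))
})

test_that("group transforms reconstruct any stack to high precision", {
    set.seed(6)
    for (b in c(4L, 8L)) {
        stack <- array(rnorm(8 * b * b), c(8, b, b))
        back <- stage1Llmmse(stack, DenoiserParams(blockSize = b),
                             sigmaPix2 = 0)
        expect_lt(max(abs(back - stack)), 1e-8)
    }
})

test_that("LLMMSE shrinks a noisy group toward structure, never expands it", {
    set.seed(7)
    base <- matrix(runif(64, 0.3, 0.7), 8)
    stack <- array(0, c(8, 8, 8))
    for (k in 1:8) stack[k, , ] <- base * matrix(rexp(64), 8)  # heavy noise
    out <- stage1Llmmse(stack, DenoiserParams(looks = 1))
    # variance across the stack must decrease: shared structure survives,
    # independent noise cancels
    v_in <- mean(apply(stack, c(2, 3), var))
    v_out <- mean(apply(out, c(2, 3), var))
    expect_lt(v_out, v_in)
})

test_that("Wiener pass limits: zero difference is identity, zero prior kills", {
    set.seed(8)
    stack <- array(runif(4 * 8 * 8, 0.2, 0.8), c(4, 8, 8))
    expect_lt(max(abs(stage2Wiener(stack, stack) - stack)), 1e-8)
    expect_equal(max(abs(stage2Wiener(stack, array(0, dim(stack))))), 0)
})

test_that("aggregation is the constant-preserving weighted mean", {
    expect_equal(aggregateEstimates(c(2, 4), c(1, 3)), 3.5)
    expect_equal(aggregateEstimates(5, 1), 5)
    expect_equal(aggregateEstimates(rep(0.7, 5), runif(5, 0.1, 1)), 0.7)
    expect_error(aggregateEstimates(c(1, 2), c(0, 0)), "weight")
})

test_that("the full filter is deterministic and shape/range preserving", {
    ph <- generatePhantom(defaultPhantomSpec(size = 64L, polarity = "bright"))
    noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 3L),
                          clip = "unit")
    p <- DenoiserParams(searchWindow = 15L, step = 4L)
    d1 <- sbm3dDenoise(noisy, p)
    d2 <- sbm3dDenoise(noisy, p)
    expect_identical(d1, d2)
    expect_equal(dim(d1), dim(noisy))
    expect_true(all(is.finite(d1)))
    expect_true(all(d1 >= 0 & d1 <= 1))
    # denoising must get closer to the clean image than the noisy input
    expect_gt(psnr(d1, ph$clean), psnr(noisy, ph$clean))
})

test_that("invalid denoiser parameterizations are rejected at construction", {
    expect_error(DenoiserParams(blockSize = 16L, searchWindow = 8L), "search")
    expect_error(DenoiserParams(maxGroup = 12L), "power of two")
    expect_error(DenoiserParams(step = 0L), "step")
    expect_error(DenoiserParams(looks = -1), "positive")
})
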