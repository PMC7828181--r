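# Phantom generator and speckle model

test_that("vessel profile follows the Gaussian cross-section exactly", {
    amp <- 0.4; sigma <- 2; bg <- 0.3
    ph <- generatePhantom(straight_vessel_spec(96L, amp, sigma, bg))
    mid <- 48.5                       # centerline between rows 48 and 49
    col <- 48
    for (row in 43:54) {
        d <- abs(row - mid)
        expect_equal(ph$clean[row, col], bg + amp * exp(-d^2 / (2 * sigma^2)),
                     tolerance = 1e-12)
    }
    # truth support is exactly the 2-sigma band
    expect_true(all(ph$truth[abs((1:96) - mid) <= 2 * sigma, col]))
    expect_false(any(ph$truth[abs((1:96) - mid) > 2 * sigma, col]))
})

test_that("empty vessel list yields a flat background and empty truth", {
    spec <- PhantomSpec(width = 32L, height = 32L, backgroundLevel = 0.5,
                        polarity = "bright", fovRadiusFraction = 1)
    ph <- generatePhantom(spec)
    expect_true(all(ph$clean[ph$fov] == 0.5))
    expect_false(any(ph$truth))
})

test_that("generation is deterministic and validates its spec", {
    a <- generatePhantom(defaultPhantomSpec(size = 64L))
    b <- generatePhantom(defaultPhantomSpec(size = 64L))
    expect_identical(a, b)
    expect_error(generatePhantom(PhantomSpec(width = 0L, height = 10L)),
                 "zero-size")
    over <- PhantomSpec(width = 32L, height = 32L, backgroundLevel = 0.9,
                        vessels = list(list(from = c(2, 16), to = c(30, 16),
                                            amp = 0.5, sigma = 2)),
                        polarity = "bright", fovRadiusFraction = 1)
    expect_warning(ph <- generatePhantom(over), "clipping")
    expect_lte(max(ph$clean), 1)
})

test_that("truth mask is always inside the FOV, dark phantoms invert bright ones", {
    for (seed in 1:3) {
        spec <- randomVesselTree(seed, size = 128L)
        ph <- generatePhantom(spec)
        expect_true(all(ph$fov[ph$truth]))
    }
    sd <- defaultPhantomSpec(size = 64L, polarity = "dark")
    sb <- defaultPhantomSpec(size = 64L, polarity = "bright")
    d <- generatePhantom(sd); b <- generatePhantom(sb)
    expect_equal(d$clean[d$fov], 1 - b$clean[b$fov])
    expect_identical(d$truth, b$truth)
})

test_that("speckle preserves zeros and vanishes for many looks", {
    z <- matrix(0, 16, 16)
    expect_equal(applySpeckle(z, NoiseSpec(looks = 1, seed = 1L)), z)
    clean <- matrix(0.5, 64, 64)
    noisy <- applySpeckle(clean, NoiseSpec(looks = 1e6, seed = 2L))
    expect_lt(sqrt(mean((noisy - clean)^2)) / 0.5, 0.01)
    expect_error(NoiseSpec(looks = 0), "positive")
})

test_that("speckle multiplier moments match the square-root-Gamma law", {
    n <- 1e6
    clean <- matrix(1, 1000, 1000)
    noisy <- applySpeckle(clean, NoiseSpec(looks = 1, seed = 5L))
    expect_lt(abs(mean(noisy) - 1), 0.005)          # unit mean, 0.5%
    # pre-normalization mean of u0 = Gamma(L + 1/2)/(Gamma(L) sqrt(L))
    m1 <- speckleMultiplierMean(1)
    expect_equal(m1, gamma(1.5), tolerance = 1e-12)
    u0 <- noisy * m1                                 # undo the rescaling
    mc_se <- stats::sd(u0) / sqrt(n)
    expect_lt(abs(mean(u0) - m1), 5 * mc_se)
})

test_that("speckle variance decreases monotonically in the number of looks", {
    clean <- matrix(1, 400, 250)                    # 1e5 samples
    v <- vapply(c(1, 2, 4, 8, 16), function(L) {
        stats::var(as.numeric(
            applySpeckle(clean, NoiseSpec(looks = L, seed = 9L))))
    }, 0.0)
    expect_true(all(diff(v) < 0))
    # and tracks the closed-form variance of the unit-mean multiplier
    expect_equal(v, vapply(c(1, 2, 4, 8, 16), speckleMultiplierVar, 0.0),
                 tolerance = 0.05)
})

test_that("same seed reproduces the noisy image bit for bit", {
    ph <- small_phantom()
    n1 <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 7L))
    n2 <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 7L))
    expect_identical(n1, n2)
    n3 <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 8L))
    expect_false(identical(n1, n3))
})
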