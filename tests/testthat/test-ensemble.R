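# Ensemble combination and the checkerboard artifact metric

test_that("a single-member ensemble reproduces the plain filter", {
    ph <- generatePhantom(defaultPhantomSpec(size = 64L, polarity = "bright"))
    noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 2L),
                          clip = "unit")
    p <- DenoiserParams(searchWindow = 15L, step = 4L)
    single <- sbm3dDenoise(noisy, p)
    ens <- ensembleDenoise(noisy, EnsembleConfig(members = list(p)))
    expect_equal(ens, single)
    # identical members collapse to one run under the mean combiner
    ens3 <- ensembleDenoise(noisy, EnsembleConfig(members = list(p, p, p)))
    expect_equal(ens3, single)
})

test_that("weights and the median combiner are honored", {
    img <- matrix(0.5, 24, 24)
    p1 <- DenoiserParams(blockSize = 4L, searchWindow = 12L, step = 2L)
    p2 <- DenoiserParams(blockSize = 8L, searchWindow = 12L, step = 4L)
    # constant image: every member returns the constant, so any weighting
    # and the median must return it too
    out_w <- ensembleDenoise(img, EnsembleConfig(members = list(p1, p2),
                                                 weights = c(0.2, 0.8)))
    expect_lt(max(abs(out_w - 0.5)), 1e-6)
    out_m <- ensembleDenoise(img, EnsembleConfig(members = list(p1, p2),
                                                 combine = "median"))
    expect_lt(max(abs(out_m - 0.5)), 1e-6)
    expect_error(EnsembleConfig(members = list(p1), weights = c(1, 2)),
                 "weights")
    expect_error(EnsembleConfig(members = list()), "at least one")
})

test_that("checkerboard energy separates block patterns from smooth images", {
    expect_equal(checkerboardEnergy(matrix(0.3, 64, 64), 8), 0)
    # exact alternating block pattern of period 8 vs a smooth ramp
    blocks <- matrix(rep(rep(c(0, 1), each = 4, length.out = 64), 64), 64,
                     byrow = TRUE)
    ramp <- matrix(rep(seq(0, 1, length.out = 64), 64), 64, byrow = TRUE)
    e_blocks <- checkerboardEnergy(blocks, 8)
    e_ramp <- checkerboardEnergy(ramp, 8)
    expect_gt(e_blocks / e_ramp, 10)
    set.seed(10)
    expect_gte(checkerboardEnergy(matrix(runif(32 * 32), 32), 6), 0)
    expect_error(checkerboardEnergy(matrix(0, 16, 16), 16), "smaller")
    expect_error(checkerboardEnergy(matrix(0, 16, 16), 1), "at least 2")
})

test_that("ensembling does not materially blur: MAE stays near the best member", {
    ph <- generatePhantom(defaultPhantomSpec(size = 96L, polarity = "bright"))
    noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 4, seed = 4L),
                          clip = "unit")
    cfg <- EnsembleConfig(members = list(
        DenoiserParams(blockSize = 4L, searchWindow = 15L),
        DenoiserParams(blockSize = 8L, searchWindow = 15L)))
    out <- ensembleDenoise(noisy, cfg, returnMembers = TRUE)
    maes <- vapply(out$members, function(m) mean(abs(m - ph$clean)), 0.0)
    mae_ens <- mean(abs(out$ensemble - ph$clean))
    expect_lte(mae_ens, 1.05 * min(maes))
})
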