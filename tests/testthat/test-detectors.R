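# Vesselness detectors: Hessian eigenanalysis, Frangi variants, line kernels

test_that("Hessian of a quadratic is exact and eigenvalues are ordered", {
    cst <- matrix(0.42, 48, 48)
    hf0 <- hessianEigen(cst, 1.5)
    expect_lt(max(abs(hf0@lambda1)), 1e-10)
    expect_lt(max(abs(hf0@lambda2)), 1e-10)

    # I(x, y) = x^2: Gaussian smoothing adds a constant, second derivatives
    # stay exact; scale-normalized eigenvalues are {0, 2 s^2}
    img <- outer(rep(1, 48), as.numeric(1:48)^2)
    hf <- hessianEigen(img, 1)
    interior <- 20:28
    expect_equal(unname(hf@ixx[interior, interior]),
                 matrix(2, 9, 9), tolerance = 1e-9)
    expect_lt(max(abs(hf@ixy[interior, interior])), 1e-9)
    expect_equal(unname(hf@lambda2[interior, interior]),
                 matrix(2, 9, 9), tolerance = 1e-9)
    expect_lt(max(abs(hf@lambda1[interior, interior])), 1e-9)

    set.seed(11)
    hfr <- hessianEigen(matrix(runif(32 * 32), 32), 2)
    expect_true(all(abs(hfr@lambda1) <= abs(hfr@lambda2) + 1e-12))
    expect_error(hessianEigen(cst, 0.3), "0.5")
})

test_that("classic Frangi follows its two-factor closed form", {
    expect_equal(max(classicFrangi(matrix(0.7, 40, 40),
                                   FrangiParams(kappa = 1))), 0)
    # an isotropic cap -(x^2+y^2)/2 has lambda1 = lambda2 = -1 at unit
    # scale: V = (1 - exp(-1/2)) (1 - exp(-1)) with alpha = kappa = 1
    n <- 41
    x <- matrix(rep(-20:20, each = n), n)
    y <- matrix(rep(-20:20, times = n), n)
    img <- -(x^2 + y^2) / 2
    v <- classicFrangi(img, FrangiParams(scales = 1, alpha = 1, kappa = 1))
    expected <- (1 - exp(-0.5)) * (1 - exp(-1))
    expect_equal(v[21, 21], expected, tolerance = 1e-6)
})

test_that("the ratio-based response hits its plateau and cubic-form values", {
    jr <- veinforge:::jerman_response
    expect_equal(jr(0.5, 1), 1)                    # lambda2 = lambda_rho / 2
    expect_equal(jr(0.25, 1), 0.648)               # lambda2 = lambda_rho / 4
    expect_equal(jr(0.25, 1), (3 / 64) * (12 / 5)^3)
    expect_equal(jr(0, 1), 0)
    expect_equal(jr(-0.3, 1), 0)
    expect_equal(jr(0.3, 0), 0)
    expect_equal(max(improvedFrangi(matrix(0.3, 40, 40))), 0)
    expect_error(improvedFrangi(matrix(runif(16), 4),
                                FrangiParams(tau = 1.2)), "tau")
})

test_that("improved Frangi stays in [0,1] and peaks on the centerline", {
    sv <- straight_vessel_image(96L, amp = 0.4, sigma = 2)
    v <- improvedFrangi(sv$img, FrangiParams(), fov = sv$fov)
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
    # per-column peak (midpoint of the argmax plateau) must sit within
    # 1 px of the true centerline at 48.5
    for (col in seq(20, 76, by = 8)) {
        peak <- mean(which(v[, col] == max(v[, col])))
        expect_lte(abs(peak - 48.5), 1.5)
    }
    # centerline response strictly exceeds far-background response
    expect_gt(min(v[48:49, 30:66]), max(v[c(1:30, 67:96), 30:66]))
})

test_that("line kernels are zero-sum with the analytic center value", {
    for (th in c(0, 30, 75, 120)) {
        k <- lineKernel(3, 4, th)
        expect_lt(abs(sum(k)), 1e-6)
        expect_equal(k, lineKernel(3, 4, th + 180))  # 180-degree symmetry
    }
    # center value g_uu(0,0) = -1/(2 pi sigmaU^3 sigmaV); the zero-sum mean
    # correction only moves it by the (negligible) kernel mean
    k <- lineKernel(2, 4, 0)
    r <- (nrow(k) + 1) / 2
    g0 <- -1 / (2 * pi * 2^3 * 4)
    expect_equal(k[r, r], g0, tolerance = 1e-5)
})

test_that("the default kernel grid has 2 x 7 x 12 members", {
    g <- lineKernelGrid(LineDetectorParams())
    expect_equal(nrow(g), 168L)
    expect_setequal(unique(g$sigmaV), c(4, 5))
    expect_equal(sort(unique(g$ratio)), seq(0.5, 3.5, by = 0.5))
    expect_equal(length(unique(g$theta)), 12L)
})

test_that("line detector zeroes constants and resolves bar orientation", {
    expect_equal(max(multiscaleLineResponse(matrix(0.6, 72, 72))), 0)
    # bright bar along the kernel's ridge axis at theta = 30 degrees:
    # the per-orientation argmax must land within one 15-degree step
    n <- 96
    X <- matrix(rep(1:n, each = n), n); Y <- matrix(rep(1:n, n), n)
    th <- 30 * pi / 180
    # ridge axis v = (sin theta, cos theta); perpendicular coordinate is u
    u <- (X - 48) * cos(th) - (Y - 48) * sin(th)
    img <- 0.2 + 0.5 * exp(-u^2 / (2 * 2^2))
    p <- LineDetectorParams(sigmaV = 4, ratios = 1)
    responses <- vapply(p@orientations, function(thd) {
        k <- lineKernel(4, 4, thd, radius = 24)
        r <- -as.numeric(EBImage::filter2(EBImage::Image(img), k,
                                          boundary = "replicate"))
        mean(matrix(r, n, n)[abs(u) < 0.5 & X > 24 & X < 72 & Y > 24 & Y < 72])
    }, 0.0)
    best <- p@orientations[which.max(responses)]
    expect_lte(min(abs(c(best - 30, best - 210, best + 150))), 15)
    expect_error(multiscaleLineResponse(matrix(0.5, 48, 48),
                                        LineDetectorParams(ratios = numeric())),
                 "positive|grid")
})

test_that("line detector peaks on the centerline above far background", {
    sv <- straight_vessel_image(96L, amp = 0.4, sigma = 2)
    v <- multiscaleLineResponse(sv$img)
    for (col in seq(24, 72, by = 8)) {
        peak <- mean(which(v[, col] == max(v[, col])))
        expect_lte(abs(peak - 48.5), 1.5)
    }
    expect_gt(min(v[48:49, 30:66]), max(v[c(1:30, 67:96), 30:66]))
})

test_that("both detectors commute with quarter-turn rotation", {
    ph <- small_phantom()
    img <- extractVesselChannel(ph$clean, "dark")
    img[!ph$fov] <- mean(img[ph$fov])
    rot <- function(m) t(m)[, nrow(m):1]          # 90 degrees clockwise
    unrot <- function(m) t(m[, ncol(m):1])
    fp <- FrangiParams()
    expect_lt(mean(abs(unrot(improvedFrangi(rot(img), fp)) -
                       improvedFrangi(img, fp))), 1e-3)
    lp <- LineDetectorParams()
    expect_lt(mean(abs(unrot(multiscaleLineResponse(rot(img), lp)) -
                       multiscaleLineResponse(img, lp))), 1e-3)
})
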