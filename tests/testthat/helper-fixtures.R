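# Shared fixtures, all generated in code.  Heavy objects are cached per test
# run so several test blocks can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixture_cache))
        assign(key, expr, envir = .fixture_cache)
    get(key, envir = .fixture_cache)
}

# a single straight horizontal bright vessel through the image center
straight_vessel_spec <- function(size = 96L, amp = 0.4, sigma = 2,
                                 bg = 0.3) {
    mid <- (size + 1) / 2
    PhantomSpec(width = size, height = size, backgroundLevel = bg,
                vessels = list(list(from = c(5, mid), to = c(size - 4, mid),
                                    amp = amp, sigma = sigma)),
                polarity = "bright", fovRadiusFraction = 1)
}

# rim-filled bright-vessel bar image for detector geometry checks (outside
# the FOV disc the generator paints black; detectors are always fed
# rim-neutralized images, as in the pipeline)
straight_vessel_image <- function(size = 96L, amp = 0.4, sigma = 2,
                                  bg = 0.3) {
    ph <- generatePhantom(straight_vessel_spec(size, amp, sigma, bg))
    img <- ph$clean
    img[!ph$fov] <- bg
    list(img = img, truth = ph$truth, fov = ph$fov)
}

# small dark-vessel phantom used across detector/pipeline tests
small_phantom <- function() {
    cached("small_phantom", generatePhantom(defaultPhantomSpec(size = 96L)))
}

# the full-size study phantom (dark vessels, 256 px)
study_phantom <- function() {
    cached("study_phantom", generatePhantom(defaultPhantomSpec(size = 256L)))
}

# independent R implementation of the patch distance (term-by-term), used
# as the oracle for the C++ path
patch_distance_oracle <- function(a_s, a_t, prior_s = NULL, prior_t = NULL,
                                  looks = 4, gamma = 0) {
    eps <- 1e-6
    a <- pmax(a_s, eps); b <- pmax(a_t, eps)
    d <- sum((2 * looks - 1) * log(a / b + b / a))
    if (gamma > 0) {
        p <- pmax(prior_s, eps); q <- pmax(prior_t, eps)
        d <- d + sum(gamma * (p - q)^2 / (p * q))
    }
    d
}

# brute-force block matcher: scores every candidate in the window with the
# oracle distance and keeps the k smallest (reference first on ties)
block_match_oracle <- function(img, ref, block, search, maxGroup, looks,
                               gamma = 0, prior = NULL) {
    h <- nrow(img); w <- ncol(img)
    half <- (search - block) %/% 2
    r0 <- max(1, ref[1] - half); r1 <- min(h - block + 1, ref[1] + half)
    c0 <- max(1, ref[2] - half); c1 <- min(w - block + 1, ref[2] + half)
    refp <- img[ref[1]:(ref[1] + block - 1), ref[2]:(ref[2] + block - 1)]
    refq <- if (gamma > 0)
        prior[ref[1]:(ref[1] + block - 1), ref[2]:(ref[2] + block - 1)]
    cand <- expand.grid(r = r0:r1, c = c0:c1)
    d <- vapply(seq_len(nrow(cand)), function(i) {
        rr <- cand$r[i]; cc <- cand$c[i]
        patch_distance_oracle(
            refp, img[rr:(rr + block - 1), cc:(cc + block - 1)],
            refq,
            if (gamma > 0) prior[rr:(rr + block - 1), cc:(cc + block - 1)],
            looks, gamma)
    }, 0.0)
    is_ref <- cand$r == ref[1] & cand$c == ref[2]
    ord <- order(d, !is_ref)          # reference wins ties at the minimum
    keep <- ord[seq_len(min(maxGroup, length(ord)))]
    list(rows = cand$r[keep], cols = cand$c[keep], dist = d[keep])
}
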