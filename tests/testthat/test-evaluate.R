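# FOV-restricted evaluation metrics

test_that("confusion metrics reproduce hand-computed Se/Sp/Acc", {
    truth <- matrix(c(rep(TRUE, 4), rep(FALSE, 6)), 2)
    perfect <- confusionMetrics(truth, truth)
    expect_equal(perfect$se, 1); expect_equal(perfect$sp, 1)
    expect_equal(perfect$acc, 1)
    flipped <- confusionMetrics(!truth, truth)
    expect_equal(flipped$se, 0); expect_equal(flipped$sp, 0)
    # TP=3 FN=1 TN=5 FP=1 -> Se 0.75, Sp 5/6, Acc 0.8
    truth <- matrix(c(rep(TRUE, 4), rep(FALSE, 6)), 2)
    pred <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5)), 2)
    cm <- confusionMetrics(pred, truth)
    expect_equal(unname(cm$counts), c(3L, 1L, 5L, 1L))
    expect_equal(cm$se, 0.75)
    expect_equal(cm$sp, 5 / 6)
    expect_equal(cm$acc, 0.8)
    expect_error(confusionMetrics(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
                 "shape")
    expect_warning(cm0 <- confusionMetrics(matrix(FALSE, 2, 2),
                                           matrix(FALSE, 2, 2)),
                   "sensitivity")
    expect_true(is.nan(cm0$se))
})

test_that("metrics ignore everything outside the FOV", {
    set.seed(17)
    truth <- matrix(runif(400) < 0.3, 20)
    pred <- matrix(runif(400) < 0.3, 20)
    fov <- matrix(FALSE, 20, 20); fov[5:16, 5:16] <- TRUE
    base <- confusionMetrics(pred, truth, fov)
    expect_equal(sum(base$counts), sum(fov))
    pred2 <- pred; truth2 <- truth
    pred2[!fov] <- !pred2[!fov]; truth2[!fov] <- !truth2[!fov]
    expect_identical(base, confusionMetrics(pred2, truth2, fov))
    scores <- matrix(runif(400), 20)
    s2 <- scores; s2[!fov] <- runif(sum(!fov))
    expect_equal(rocAuc(scores, truth, fov), rocAuc(s2, truth, fov))
})

test_that("AUC matches the concordant-pair counting oracle with ties", {
    auc_oracle <- function(s, y) {
        pos <- s[y]; neg <- s[!y]
        pairs <- expand.grid(p = pos, n = neg)
        (sum(pairs$p > pairs$n) + 0.5 * sum(pairs$p == pairs$n)) /
            nrow(pairs)
    }
    # 6-pixel toy with one tie
    s <- matrix(c(0.9, 0.8, 0.5, 0.5, 0.3, 0.1), 2)
    y <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
    expect_equal(rocAuc(s, y), auc_oracle(as.numeric(s), as.logical(y)))
    set.seed(18)
    for (i in 1:25) {
        s <- matrix(sample(seq(0, 1, by = 0.1), 30, TRUE), 5)
        y <- matrix(runif(30) < 0.4, 5)
        if (sum(y) == 0 || sum(!y) == 0) next
        expect_equal(rocAuc(s, y), auc_oracle(as.numeric(s), as.logical(y)))
    }
    # limits and invariances
    sep <- matrix(c(rep(1, 3), rep(0, 3)), 2)
    ysep <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), 2)
    expect_equal(rocAuc(sep, ysep), 1)
    expect_equal(rocAuc(matrix(0.5, 2, 3), ysep), 0.5)
    set.seed(19)
    s <- matrix(runif(100), 10); y <- matrix(runif(100) < 0.5, 10)
    expect_equal(rocAuc(s, y), rocAuc(exp(3 * s), y))   # monotone transform
    expect_error(rocAuc(s, matrix(TRUE, 10, 10)), "both classes")
})

test_that("Dice agrees with its confusion-count definition", {
    truth <- matrix(c(rep(TRUE, 4), rep(FALSE, 6)), 2)
    pred <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5)), 2)
    expect_equal(diceCoefficient(pred, truth), 2 * 3 / (2 * 3 + 1 + 1))
    expect_equal(diceCoefficient(truth, truth), 1)
})
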