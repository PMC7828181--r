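# Evaluation metrics, computed strictly inside the field of view.

#' Confusion counts and Se/Sp/Acc
#'
#' Tallies TP/FP/TN/FN over field-of-view pixels only (any nonzero
#' ground-truth pixel counts as vessel, accommodating the differing mask
#' encodings of the public datasets) and derives sensitivity
#' \code{TP/(TP+FN)}, specificity \code{TN/(TN+FP)} and accuracy
#' \code{(TP+TN)/(TP+FN+TN+FP)}.  A zero denominator yields \code{NaN} with
#' a warning.
#'
#' @param pred predicted binary mask (logical or numeric matrix).
#' @param truth ground-truth mask.
#' @param fov optional field-of-view mask; all pixels when absent.
#' @return list with \code{counts} (named TP/FP/TN/FN), \code{se},
#'   \code{sp}, \code{acc}.
#' @examples
#' p <- matrix(c(TRUE, TRUE, FALSE), 1); t <- matrix(c(TRUE, FALSE, FALSE), 1)
#' confusionMetrics(p, t)$acc
#' @export
confusionMetrics <- function(pred, truth, fov = NULL) {
    assert_same_shape(pred, truth)
    if (is.null(fov)) fov <- matrix(TRUE, nrow(pred), ncol(pred))
    assert_same_shape(pred, fov)
    f <- as_mask(fov)
    p <- as_mask(pred)[f]
    t <- as_mask(truth)[f]
    tp <- sum(p & t); fp <- sum(p & !t)
    tn <- sum(!p & !t); fn <- sum(!p & t)
    ratio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (zero denominator)")
            return(NaN)
        }
        num / den
    }
    list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
         se = ratio(tp, tp + fn, "sensitivity"),
         sp = ratio(tn, tn + fp, "specificity"),
         acc = ratio(tp + tn, tp + fp + tn + fn, "accuracy"))
}

#' Area under the ROC curve
#'
#' AUC of the continuous vesselness score against the ground truth over
#' field-of-view pixels, computed by the rank (Mann-Whitney) identity with
#' midrank tie handling -- exactly the trapezoidal area of the ROC curve
#' through tied score groups.
#'
#' @param vmap numeric score matrix.
#' @param truth ground-truth mask.
#' @param fov optional field-of-view mask.
#' @return scalar in [0, 1].
#' @export
rocAuc <- function(vmap, truth, fov = NULL) {
    assert_same_shape(vmap, truth)
    if (is.null(fov)) fov <- matrix(TRUE, nrow(vmap), ncol(vmap))
    f <- as_mask(fov)
    s <- vmap[f]
    y <- as_mask(truth)[f]
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 == 0 || n0 == 0)
        stop("both classes must be present inside the FOV")
    r <- rank(s, ties.method = "average")
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dice overlap coefficient
#'
#' \code{2 TP / (2 TP + FP + FN)} between predicted and true vessel masks
#' within the field of view.
#'
#' @inheritParams confusionMetrics
#' @return scalar in [0, 1] (\code{NaN} when both masks are empty).
#' @export
diceCoefficient <- function(pred, truth, fov = NULL) {
    cm <- suppressWarnings(confusionMetrics(pred, truth, fov))
    cts <- cm$counts
    den <- 2 * cts["TP"] + cts["FP"] + cts["FN"]
    unname(if (den == 0) NaN else 2 * cts["TP"] / den)
}
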