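# Ensemble of S-BM3D filters: the artifact-suppression mechanism.  Members
# differ in block size and search window, so their block-locked checkerboard
# patterns are mutually de-phased and average out, while the vessel signal
# they share survives the average.

#' Default 4-member ensemble grid
#'
#' Block size in \{4, 8\} crossed with search window in \{24, 39\}, uniform
#' weights, mean combine.  The small-block members carry fine detail, the
#' large-block members smoothness; their artifact patterns differ in period
#' and phase, which is what the average exploits.
#'
#' @param looks number of looks L shared by all members.
#' @param ... further arguments passed to every member's
#'   \code{\link{DenoiserParams}}.
#' @return an \code{\link{EnsembleConfig}}.
#' @export
defaultEnsemble <- function(looks = 4, ...) {
    grid <- expand.grid(block = c(4L, 8L), search = c(24L, 39L))
    members <- lapply(seq_len(nrow(grid)), function(i)
        DenoiserParams(blockSize = grid$block[i],
                       searchWindow = grid$search[i], looks = looks, ...))
    EnsembleConfig(members = members)
}

#' Ensemble S-BM3D denoising
#'
#' Runs every member filter on the same image and combines the outputs
#' pixelwise by weighted mean (or median).  Deterministic; a failing member
#' aborts with its parameters in the message.
#'
#' @param img numeric matrix in [0,1].
#' @param cfg an \code{\link{EnsembleConfig}}.
#' @param twoStage passed to each member (\code{FALSE} stops after the
#'   LLMMSE pass).
#' @param returnMembers also return the individual member outputs.
#' @return the combined image, or (with \code{returnMembers = TRUE}) a list
#'   with elements \code{ensemble} and \code{members}.
#' @seealso \code{\link{checkerboardEnergy}} for the artifact metric the
#'   ensemble is designed to reduce.
#' @export
ensembleDenoise <- function(img, cfg = defaultEnsemble(), twoStage = TRUE,
                            returnMembers = FALSE) {
    validObject(cfg)
    outs <- lapply(cfg@members, function(p) {
        tryCatch(sbm3dDenoise(img, p, twoStage = twoStage),
                 error = function(e) stop(sprintf(
                     "ensemble member (block %d, search %d) failed: %s",
                     p@blockSize, p@searchWindow, conditionMessage(e)),
                     call. = FALSE))
    })
    n <- length(outs)
    if (cfg@combine == "median") {
        stacked <- array(unlist(outs), dim = c(dim(img), n))
        comb <- apply(stacked, c(1, 2), median)
    } else {
        w <- if (length(cfg@weights)) cfg@weights else rep(1, n)
        w <- w / sum(w)
        comb <- Reduce(`+`, Map(`*`, outs, as.list(w)))
    }
    if (returnMembers) list(ensemble = comb, members = outs) else comb
}

#' Checkerboard artifact energy
#'
#' Fraction of the image's AC spectral power concentrated in narrow bands
#' around the spatial frequencies \code{1/period} and \code{2/period} along
#' either axis.  Block-matching denoisers leave periodic artifacts locked to
#' the block geometry, which show up exactly there; a constant image scores
#' zero.
#'
#' @param img numeric matrix.
#' @param period artifact period in pixels (typically the block size);
#'   at least 2 and smaller than the image side.
#' @param bandwidth half-width of the frequency band in cycles/pixel;
#'   defaults to 1.5 DFT bins of the smaller image side.
#' @return nonnegative scalar (0 when the image has no AC power).
#' @export
checkerboardEnergy <- function(img, period, bandwidth = NULL) {
    assert_image(img)
    if (period < 2) stop("period must be at least 2")
    h <- nrow(img); w <- ncol(img)
    if (period >= min(h, w)) stop("period must be smaller than the image side")
    if (is.null(bandwidth)) bandwidth <- 1.5 / min(h, w)
    x <- img - mean(img)
    p <- Mod(fft(x))^2
    total <- sum(p)
    if (total <= 0) return(0)
    fy <- (seq_len(h) - 1) / h; fy <- pmin(fy, 1 - fy)
    fx <- (seq_len(w) - 1) / w; fx <- pmin(fx, 1 - fx)
    targets <- c(1 / period, min(2 / period, 0.5))
    near <- function(f) Reduce(`|`, lapply(targets, function(t0)
        abs(f - t0) <= bandwidth))
    band <- outer(near(fy), rep(TRUE, w)) | outer(rep(TRUE, h), near(fx))
    band[1, 1] <- FALSE
    sum(p[band]) / total
}
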