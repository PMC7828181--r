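# small shared helpers

clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_image <- function(img, name = "img") {
    if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img)))
        stop(name, " must be a finite numeric matrix", call. = FALSE)
    invisible(img)
}

assert_same_shape <- function(...) {
    dims <- lapply(list(...), dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        stop("image shapes do not match", call. = FALSE)
    invisible(NULL)
}

as_mask <- function(m) {
    if (is.logical(m)) return(m)
    out <- m != 0
    dim(out) <- dim(m)
    out
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
    expr <- substitute(expr)
    pf <- parent.frame()
    if (is.null(seed) || is.na(seed)) return(eval(expr, pf))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    eval(expr, pf)
}

# symmetric (mirror-with-edge) padding of a matrix by p pixels on every side
pad_symmetric <- function(m, p) {
    if (p == 0L) return(m)
    h <- nrow(m); w <- ncol(m)
    if (p > h || p > w) stop("padding exceeds image size")
    ri <- c(p:1, 1:h, h:(h - p + 1))
    ci <- c(p:1, 1:w, w:(w - p + 1))
    m[ri, ci, drop = FALSE]
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} between an image and a reference, in dB.
#'
#' @param x,ref numeric matrices of the same shape.
#' @param peak signal peak (1 for images in [0,1]).
#' @param mask optional logical matrix restricting the comparison.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, ref, peak = 1, mask = NULL) {
    assert_same_shape(x, ref)
    d <- x - ref
    if (!is.null(mask)) d <- d[as_mask(mask)]
    mse <- mean(d^2)
    if (mse == 0) return(Inf)
    10 * log10(peak^2 / mse)
}
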