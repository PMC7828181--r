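# Raster I/O: PNG (png), TIFF (tiff, if installed) and plain PNM/PPM.
# Images come back as numeric matrices/arrays in [0,1]; masks as logical
# matrices written as 0/255 binary PNG.

read_pnm <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 2L)
    if (!magic %in% c("P2", "P3", "P5", "P6"))
        stop("unsupported PNM magic: ", magic)
    tokens <- character()
    # header: width, height, maxval; '#' starts a comment
    while (length(tokens) < 3L) {
        ch <- readChar(con, 1L)
        if (!length(ch)) stop("truncated PNM header")
        if (ch == "#") {
            repeat {
                ch <- readChar(con, 1L)
                if (!length(ch) || ch == "\n") break
            }
        } else if (grepl("[0-9]", ch)) {
            tok <- ch
            repeat {
                ch <- readChar(con, 1L)
                if (!length(ch) || !grepl("[0-9]", ch)) break
                tok <- paste0(tok, ch)
            }
            tokens <- c(tokens, tok)
        }
    }
    w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
    mx <- as.integer(tokens[3])
    nch <- if (magic %in% c("P3", "P6")) 3L else 1L
    n <- w * h * nch
    vals <- if (magic %in% c("P5", "P6")) {
        if (mx < 256) {
            as.integer(readBin(con, "raw", n))
        } else {
            readBin(con, "integer", n, size = 2, signed = FALSE,
                    endian = "big")
        }
    } else {
        scan(con, what = integer(), n = n, quiet = TRUE)
    }
    v <- vals / mx
    if (nch == 1L) {
        matrix(v, h, w, byrow = TRUE)
    } else {
        arr <- array(0, dim = c(h, w, 3))
        for (c in 1:3)
            arr[, , c] <- matrix(v[seq(c, n, by = 3)], h, w, byrow = TRUE)
        arr
    }
}

#' Read a fundus image
#'
#' Reads PNG, TIFF or PNM/PPM/PGM rasters into a numeric matrix (grayscale)
#' or H x W x 3 array (color) in [0,1]; an alpha channel is dropped.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix or array in [0,1].
#' @export
readFundusImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = png::readPNG(path),
        tif = , tiff = {
            if (!requireNamespace("tiff", quietly = TRUE))
                stop("the 'tiff' package is required to read TIFF files")
            tiff::readTIFF(path)
        },
        pnm = , pgm = , ppm = read_pnm(path),
        stop("unsupported image format: .", ext))
    if (is.array(img) && length(dim(img)) == 3L) {
        if (dim(img)[3] >= 3L) img <- img[, , 1:3] else img <- img[, , 1]
    }
    img
}

#' Write a grayscale image as PNG
#'
#' @param img numeric matrix; values are clipped to [0,1].
#' @param path output path.
#' @export
writeImagePNG <- function(img, path) {
    png::writePNG(clamp01(img), path)
    invisible(path)
}

#' Read a binary mask
#'
#' Any pixel above half intensity counts as foreground (the public datasets
#' encode masks variously as 0/1 and 0/255).
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
readMaskPNG <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
}

#' Write a binary mask as 0/255 PNG
#'
#' @param mask logical (or numeric) matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
    png::writePNG(as_mask(mask) * 1, path)
    invisible(path)
}
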