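# End-to-end segmentation pipeline: channel extraction -> CLAHE -> ensemble
# S-BM3D -> vesselness detector -> anisotropic diffusion -> ISODATA
# threshold -> binary mask.  Deterministic for fixed input and config.

#' Segment retinal vessels
#'
#' Runs the full unsupervised pipeline on a fundus image (color array,
#' grayscale matrix or a file path readable by
#' \code{\link{readFundusImage}}).  The field-of-view mask is taken from
#' \code{fov} when supplied (bypassing estimation entirely) and estimated
#' from the image otherwise.  Every stage's parameters and the converged
#' threshold are recorded in the run log.
#'
#' @param img numeric matrix, H x W x 3 array, or file path.
#' @param fov optional field-of-view mask (logical matrix or file path).
#' @param config a \code{\link{PipelineConfig}}.
#' @return a \code{\linkS4class{SegmentationResult}}; the mask is
#'   \code{FALSE} everywhere outside the FOV.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(size = 96L))
#' noisy <- applySpeckle(ph$clean, NoiseSpec(looks = 8, seed = 1L), clip = "unit")
#' cfg <- PipelineConfig(denoise = FALSE)  # fast: detector stages only
#' res <- segmentVessels(noisy, fov = ph$fov, config = cfg)
#' thresholdValue(res)
#' @export
segmentVessels <- function(img, fov = NULL, config = PipelineConfig()) {
    validObject(config)
    if (is.character(img)) img <- readFundusImage(img)
    if (is.character(fov)) fov <- readMaskPNG(fov)

    stage <- "channel extraction"
    result <- tryCatch({
        channel <- extractVesselChannel(img, config@polarity)

        if (is.null(fov)) {
            stage <- "FOV estimation"
            fov_src <- if (is.matrix(img)) img else img[, , 1]
            fov <- estimateFov(fov_src, config@fovThresholdFraction)
        } else {
            fov <- as_mask(fov)
        }
        assert_same_shape(channel, fov)

        # neutralize the rim: the dark border outside the FOV would otherwise
        # imprint a massive artificial edge on the detectors and on the
        # denoiser's patch statistics
        channel[!fov] <- mean(channel[fov])

        stage <- "CLAHE"
        enhanced <- claheEnhance(channel, fov, config@clahe)
        enhanced[!fov] <- mean(enhanced[fov])

        stage <- "denoising"
        ens <- config@ensemble
        looksHat <- NA_real_
        if (config@denoise && config@autoLooks) {
            looksHat <- estimateLooks(enhanced, fov)
            ens@members <- lapply(ens@members, function(m) {
                m@looks <- looksHat
                m
            })
        }
        denoised <- if (config@denoise) {
            ensembleDenoise(enhanced, ens, twoStage = !config@singleStage)
        } else enhanced

        if (config@diffusionStage == "pre") {
            stage <- "anisotropic diffusion"
            denoised <- anisotropicDiffusion(denoised, config@diffusion)
        }

        stage <- paste0("detector (", config@detector, ")")
        vmap <- if (config@detector == "frangi") {
            improvedFrangi(denoised, config@frangi, fov = fov)
        } else {
            multiscaleLineResponse(denoised, config@line)
        }

        if (config@diffusionStage == "post") {
            stage <- "anisotropic diffusion"
            vmap <- anisotropicDiffusion(vmap, config@diffusion)
        }

        stage <- "ISODATA threshold"
        thr <- isodataThreshold(vmap, mask = fov)

        stage <- "binarization"
        mask <- binarize(vmap, as.numeric(thr), fov)
        if (config@minComponent > 0L) {
            lab <- EBImage::bwlabel(mask)
            sizes <- tabulate(lab[lab > 0])
            keep <- which(sizes >= config@minComponent)
            mask <- matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
        }
        list(mask = mask, vmap = vmap, thr = thr, looksHat = looksHat)
    }, error = function(e) {
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE)
    })

    log <- list(
        polarity = config@polarity,
        clahe = list(tiles = config@clahe@tiles,
                     clipLimit = config@clahe@clipLimit,
                     nBins = config@clahe@nBins),
        denoise = config@denoise,
        singleStage = config@singleStage,
        autoLooks = config@autoLooks,
        estimatedLooks = result$looksHat,
        ensembleMembers = if (config@denoise) lapply(
            config@ensemble@members, function(m) list(
                blockSize = m@blockSize, searchWindow = m@searchWindow,
                step = m@step, maxGroup = m@maxGroup, looks = m@looks,
                gamma = m@gamma, levels = m@levels)) else list(),
        detector = config@detector,
        detectorParams = if (config@detector == "frangi") list(
            scales = config@frangi@scales, tau = config@frangi@tau) else list(
            sigmaV = config@line@sigmaV, ratios = config@line@ratios,
            orientations = config@line@orientations,
            alpha = config@line@alpha, beta = config@line@beta),
        diffusion = list(iterations = config@diffusion@iterations,
                         kappa = config@diffusion@kappa,
                         dt = config@diffusion@dt,
                         conduction = config@diffusion@conduction,
                         stage = config@diffusionStage),
        threshold = as.numeric(result$thr),
        thresholdIterations = attr(result$thr, "iterations"),
        minComponent = config@minComponent)

    new("SegmentationResult", mask = result$mask, vesselness = result$vmap,
        fov = fov, threshold = as.numeric(result$thr), log = log)
}
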