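# S4 parameter and result classes.  Constructors of the same name supply the
# package defaults; validity methods enforce every structural invariant so a
# bad configuration fails at construction, not three stages into a run.

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# -- denoiser ----------------------------------------------------------------

#' S-BM3D denoiser parameterization
#'
#' One parameterization of the speckle-adapted BM3D filter.  \code{blockSize}
#' and \code{searchWindow} are the two knobs the ensemble varies; the
#' remaining fields follow the SAR despeckling conventions for this filter
#' family.
#'
#' @param blockSize side of the square patch, pixels.
#' @param searchWindow side of the square matching neighborhood, pixels;
#'   must be at least \code{blockSize}.
#' @param step stride between reference patches, pixels; must not exceed
#'   \code{blockSize} so every pixel is covered by at least one group.
#' @param maxGroup maximum number of patches per group; a power of two (the
#'   orthonormal Haar transform runs along the stacking axis).
#' @param looks number of looks L of the speckle model (larger L, weaker
#'   speckle); positive real.
#' @param gamma weight of the prior term in the patch distance used by the
#'   second (Wiener) pass; nonnegative.
#' @param wavelet redundant spatial wavelet identifier; currently the 8-tap
#'   Daubechies filter \code{"daub8"}.
#' @param levels decomposition depth of the redundant wavelet.
#' @param groupTransform 1-D orthonormal transform along the stacking axis;
#'   currently \code{"haar"}.
#' @return a \code{DenoiserParams} object.
#' @examples
#' DenoiserParams(blockSize = 4L, searchWindow = 24L)
#' @export DenoiserParams
#' @exportClass DenoiserParams
#' @aliases DenoiserParams-class
setClass("DenoiserParams", representation(
    blockSize = "integer", searchWindow = "integer", step = "integer",
    maxGroup = "integer", looks = "numeric", gamma = "numeric",
    wavelet = "character", levels = "integer", groupTransform = "character"))

setValidity("DenoiserParams", function(object) {
    msg <- character()
    if (object@blockSize < 2L) msg <- c(msg, "blockSize must be >= 2")
    if (object@searchWindow < object@blockSize)
        msg <- c(msg, "blockSize must not exceed searchWindow")
    if (object@step < 1L || object@step > object@blockSize)
        msg <- c(msg, "step must lie in [1, blockSize] for full coverage")
    if (!is_pow2(object@maxGroup) || object@maxGroup > 64L)
        msg <- c(msg, "maxGroup must be a power of two in [1, 64]")
    if (!is.finite(object@looks) || object@looks <= 0)
        msg <- c(msg, "looks must be positive")
    if (!is.finite(object@gamma) || object@gamma < 0)
        msg <- c(msg, "gamma must be nonnegative")
    if (object@wavelet != "daub8") msg <- c(msg, "unknown wavelet")
    if (object@groupTransform != "haar") msg <- c(msg, "unknown group transform")
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (length(msg)) msg else TRUE
})

DenoiserParams <- function(blockSize = 8L, searchWindow = 39L, step = 3L,
                           maxGroup = 16L, looks = 4, gamma = 4,
                           wavelet = "daub8", levels = 2L,
                           groupTransform = "haar") {
    new("DenoiserParams", blockSize = as.integer(blockSize),
        searchWindow = as.integer(searchWindow), step = as.integer(step),
        maxGroup = as.integer(maxGroup), looks = as.numeric(looks),
        gamma = as.numeric(gamma), wavelet = wavelet,
        levels = as.integer(levels), groupTransform = groupTransform)
}

#' Ensemble of S-BM3D parameterizations
#'
#' The ensemble denoiser runs every member filter on the same image and
#' combines the outputs pixelwise; varying block size and search window
#' across members de-phases the block-locked checkerboard artifacts so the
#' average suppresses them while each member still contributes its recovered
#' detail.
#'
#' @param members list of \code{\link{DenoiserParams}}; at least one.
#' @param combine \code{"mean"} (weighted) or \code{"median"}.
#' @param weights nonnegative member weights; empty for uniform.  Ignored by
#'   the median combiner.
#' @return an \code{EnsembleConfig} object.
#' @seealso \code{\link{defaultEnsemble}} for the default 4-member grid.
#' @export EnsembleConfig
#' @exportClass EnsembleConfig
#' @aliases EnsembleConfig-class
setClass("EnsembleConfig", representation(
    members = "list", combine = "character", weights = "numeric"))

setValidity("EnsembleConfig", function(object) {
    msg <- character()
    if (length(object@members) < 1L) msg <- c(msg, "need at least one member")
    if (!all(vapply(object@members, is, TRUE, "DenoiserParams")))
        msg <- c(msg, "members must all be DenoiserParams")
    if (!object@combine %in% c("mean", "median"))
        msg <- c(msg, "combine must be 'mean' or 'median'")
    if (length(object@weights) &&
        (length(object@weights) != length(object@members) ||
         any(object@weights < 0) || sum(object@weights) <= 0))
        msg <- c(msg, "weights must match members, be nonnegative, sum > 0")
    if (length(msg)) msg else TRUE
})

EnsembleConfig <- function(members, combine = "mean", weights = numeric()) {
    new("EnsembleConfig", members = members, combine = combine,
        weights = as.numeric(weights))
}

# -- phantom -----------------------------------------------------------------

#' Synthetic fundus phantom specification
#'
#' Describes a phantom image: a flat background inside a circular field of
#' view, crossed by vessels with Gaussian cross-sections.  Each element of
#' \code{vessels} is a list with fields \code{from} and \code{to} (c(x, y)
#' endpoints, pixel units), optional \code{ctrl} (a quadratic Bezier control
#' point), \code{amp} (centerline amplitude above background, in [0,1]) and
#' \code{sigma} (cross-section standard deviation, pixels).  The ground-truth
#' vessel support is the set of pixels within \code{2 * sigma} of a
#' centerline, intersected with the field of view.
#'
#' @param width,height image size in pixels.
#' @param backgroundLevel flat background intensity in [0,1] (of the
#'   bright-vessel rendering; dark phantoms are produced by inversion).
#' @param vessels list of vessel segment descriptions (see Details).
#' @param polarity \code{"bright"} for vessels brighter than background,
#'   \code{"dark"} (realistic fundus) for the inverted rendering.
#' @param fovRadiusFraction field-of-view disc radius as a fraction of
#'   \code{min(width, height) / 2}.
#' @param seed integer; reserved for randomized layouts
#'   (\code{\link{randomVesselTree}}) -- the rendered phantom itself is a
#'   deterministic function of the spec.
#' @return a \code{PhantomSpec} object.
#' @seealso \code{\link{generatePhantom}}, \code{\link{defaultPhantomSpec}}
#' @export PhantomSpec
#' @exportClass PhantomSpec
#' @aliases PhantomSpec-class
setClass("PhantomSpec", representation(
    width = "integer", height = "integer", backgroundLevel = "numeric",
    vessels = "list", polarity = "character", fovRadiusFraction = "numeric",
    seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (object@width < 1L || object@height < 1L)
        msg <- c(msg, "zero-size image")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
        msg <- c(msg, "backgroundLevel must be in [0,1]")
    if (!object@polarity %in% c("bright", "dark"))
        msg <- c(msg, "polarity must be 'bright' or 'dark'")
    if (object@fovRadiusFraction <= 0 || object@fovRadiusFraction > 1)
        msg <- c(msg, "fovRadiusFraction must be in (0,1]")
    for (v in object@vessels) {
        if (!all(c("from", "to", "amp", "sigma") %in% names(v))) {
            msg <- c(msg, "each vessel needs from, to, amp, sigma")
            break
        }
        if (v$amp < 0 || v$amp > 1) msg <- c(msg, "vessel amp must be in [0,1]")
        if (v$sigma <= 0) msg <- c(msg, "vessel sigma must be positive")
    }
    if (length(msg)) msg else TRUE
})

PhantomSpec <- function(width = 256L, height = 256L, backgroundLevel = 0.4,
                        vessels = list(), polarity = "dark",
                        fovRadiusFraction = 0.94, seed = 1L) {
    new("PhantomSpec", width = as.integer(width), height = as.integer(height),
        backgroundLevel = as.numeric(backgroundLevel), vessels = vessels,
        polarity = polarity, fovRadiusFraction = as.numeric(fovRadiusFraction),
        seed = as.integer(seed))
}

#' Speckle / additive noise specification
#'
#' Multiplicative L-look amplitude speckle: each pixel is multiplied by an
#' independent draw \code{u} with \code{u^2 ~ Gamma(shape = L, scale = 1/L)},
#' rescaled to unit mean so the expected noisy image equals the clean one.
#' Optional additive Gaussian noise of standard deviation
#' \code{additiveSigma} is applied afterwards.
#'
#' @param looks number of looks L; positive (larger L, lower speckle
#'   variance).
#' @param additiveSigma additive Gaussian standard deviation in intensity
#'   units; 0 disables.
#' @param seed integer RNG seed; \code{NA} draws from the current RNG state.
#' @return a \code{NoiseSpec} object.
#' @seealso \code{\link{applySpeckle}}
#' @export NoiseSpec
#' @exportClass NoiseSpec
#' @aliases NoiseSpec-class
setClass("NoiseSpec", representation(
    looks = "numeric", additiveSigma = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
    msg <- character()
    if (!is.finite(object@looks) || object@looks <= 0)
        msg <- c(msg, "looks must be positive")
    if (is.na(object@additiveSigma) || object@additiveSigma < 0)
        msg <- c(msg, "additiveSigma must be >= 0")
    if (length(msg)) msg else TRUE
})

NoiseSpec <- function(looks = 4, additiveSigma = 0, seed = NA_integer_) {
    new("NoiseSpec", looks = as.numeric(looks),
        additiveSigma = as.numeric(additiveSigma), seed = as.integer(seed))
}

# -- preprocessing -----------------------------------------------------------

#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization: the image is divided
#' into a grid of tiles, a clipped histogram mapping is computed per tile
#' (restricted to field-of-view pixels when a mask is supplied) and pixel
#' mappings are bilinearly interpolated between neighboring tiles.
#'
#' @param tiles integer (rows, cols) tile grid; the canonical default is 8x8.
#' @param clipLimit histogram clip limit as a multiple of the mean bin count;
#'   positive.
#' @param nBins number of histogram bins.
#' @return a \code{ClaheParams} object.
#' @export ClaheParams
#' @exportClass ClaheParams
#' @aliases ClaheParams-class
setClass("ClaheParams", representation(
    tiles = "integer", clipLimit = "numeric", nBins = "integer"))

setValidity("ClaheParams", function(object) {
    msg <- character()
    if (length(object@tiles) != 2L || any(object@tiles < 1L))
        msg <- c(msg, "tiles must be two integers >= 1")
    if (!is.finite(object@clipLimit) || object@clipLimit <= 0)
        msg <- c(msg, "clipLimit must be positive")
    if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
    if (length(msg)) msg else TRUE
})

ClaheParams <- function(tiles = c(8L, 8L), clipLimit = 2.0, nBins = 256L) {
    new("ClaheParams", tiles = as.integer(tiles),
        clipLimit = as.numeric(clipLimit), nBins = as.integer(nBins))
}

# -- detectors ---------------------------------------------------------------

#' Hessian eigenvalue field
#'
#' Scale-normalized Gaussian second derivatives and the per-pixel ordered
#' eigenvalues (\code{abs(lambda1) <= abs(lambda2)}) of the 2x2 Hessian at
#' one scale.
#'
#' @seealso \code{\link{hessianEigen}}
#' @exportClass HessianField
#' @aliases HessianField-class
setClass("HessianField", representation(
    ixx = "matrix", ixy = "matrix", iyy = "matrix",
    lambda1 = "matrix", lambda2 = "matrix", scale = "numeric"))

#' Frangi-type vesselness parameters
#'
#' Parameters shared by the classic two-factor Frangi filter and the
#' eigenvalue-ratio (improved) variant.  \code{tau} is the cutoff of the
#' ratio-based regularization in [0,1]; \code{alpha} and \code{kappa} only
#' affect the classic variant (a \code{kappa} of \code{NA} uses half the
#' maximum structureness at each scale).
#'
#' @param scales Gaussian scales in pixels, all positive.
#' @param tau ratio-filter cutoff threshold in [0,1].
#' @param alpha classic-variant sensitivity of the eigenvalue-ratio factor.
#' @param kappa classic-variant sensitivity of the structureness factor.
#' @return a \code{FrangiParams} object.
#' @export FrangiParams
#' @exportClass FrangiParams
#' @aliases FrangiParams-class
setClass("FrangiParams", representation(
    scales = "numeric", tau = "numeric", alpha = "numeric", kappa = "numeric"))

setValidity("FrangiParams", function(object) {
    msg <- character()
    if (!length(object@scales) || any(object@scales <= 0))
        msg <- c(msg, "scales must be positive")
    if (is.na(object@tau) || object@tau < 0 || object@tau > 1)
        msg <- c(msg, "tau must be in [0,1]")
    if (!is.finite(object@alpha) || object@alpha <= 0)
        msg <- c(msg, "alpha must be positive")
    if (length(msg)) msg else TRUE
})

FrangiParams <- function(scales = c(2, 3, 4.5, 6), tau = 0.5,
                         alpha = 0.5, kappa = NA_real_) {
    new("FrangiParams", scales = as.numeric(scales), tau = as.numeric(tau),
        alpha = as.numeric(alpha), kappa = as.numeric(kappa))
}

#' Multiscale line detector parameters
#'
#' Oriented anisotropic Gaussian second-derivative kernels: elongation
#' \code{sigmaU = ratio * sigmaV} for every width \code{sigmaV}, length
#' ratio and orientation; the per-pixel detector response is the maximum of
#' the scale-normalized (\code{sigmaU^alpha * sigmaV^beta}) negated kernel
#' responses over the whole grid.
#'
#' @param sigmaV widths in pixels (default the set \{4, 5\}).
#' @param ratios elongation multiples of \code{sigmaV}
#'   (default 0.5, 1, ..., 3.5).
#' @param orientations kernel orientations in degrees, within [0, 180).
#' @param alpha,beta scale-normalization exponents (defaults 1 and 0.5,
#'   chosen to favor thin low-contrast vessels).
#' @return a \code{LineDetectorParams} object.
#' @export LineDetectorParams
#' @exportClass LineDetectorParams
#' @aliases LineDetectorParams-class
setClass("LineDetectorParams", representation(
    sigmaV = "numeric", ratios = "numeric", orientations = "numeric",
    alpha = "numeric", beta = "numeric"))

setValidity("LineDetectorParams", function(object) {
    msg <- character()
    if (!length(object@sigmaV) || any(object@sigmaV <= 0))
        msg <- c(msg, "sigmaV must be positive")
    if (!length(object@ratios) || any(object@ratios <= 0))
        msg <- c(msg, "ratios must be positive")
    if (!length(object@orientations) ||
        any(object@orientations < 0 | object@orientations >= 180))
        msg <- c(msg, "orientations must lie in [0, 180)")
    if (length(msg)) msg else TRUE
})

LineDetectorParams <- function(sigmaV = c(4, 5),
                               ratios = seq(0.5, 3.5, by = 0.5),
                               orientations = seq(0, 165, by = 15),
                               alpha = 1, beta = 0.5) {
    new("LineDetectorParams", sigmaV = as.numeric(sigmaV),
        ratios = as.numeric(ratios), orientations = as.numeric(orientations),
        alpha = as.numeric(alpha), beta = as.numeric(beta))
}

# -- postprocessing ----------------------------------------------------------

#' Perona-Malik anisotropic diffusion parameters
#'
#' @param iterations number of diffusion steps.
#' @param kappa edge-stopping constant in intensity units: gradients well
#'   below \code{kappa} diffuse, gradients well above are preserved.
#' @param dt time step; must lie in (0, 0.25] for 4-neighbor stability.
#' @param conduction \code{"exponential"} (\code{exp(-(g/kappa)^2)}) or
#'   \code{"rational"} (\code{1/(1+(g/kappa)^2)}).
#' @return a \code{DiffusionParams} object.
#' @export DiffusionParams
#' @exportClass DiffusionParams
#' @aliases DiffusionParams-class
setClass("DiffusionParams", representation(
    iterations = "integer", kappa = "numeric", dt = "numeric",
    conduction = "character"))

setValidity("DiffusionParams", function(object) {
    msg <- character()
    if (object@iterations < 0L) msg <- c(msg, "iterations must be >= 0")
    if (!is.finite(object@kappa) || object@kappa <= 0)
        msg <- c(msg, "kappa must be positive")
    if (is.na(object@dt) || object@dt <= 0 || object@dt > 0.25)
        msg <- c(msg, "dt must lie in (0, 0.25]")
    if (!object@conduction %in% c("exponential", "rational"))
        msg <- c(msg, "conduction must be 'exponential' or 'rational'")
    if (length(msg)) msg else TRUE
})

DiffusionParams <- function(iterations = 30L, kappa = 0.1, dt = 0.2,
                            conduction = "exponential") {
    new("DiffusionParams", iterations = as.integer(iterations),
        kappa = as.numeric(kappa), dt = as.numeric(dt),
        conduction = conduction)
}

# -- pipeline ----------------------------------------------------------------

#' End-to-end pipeline configuration
#'
#' Bundles the parameters of every stage of the segmentation pipeline:
#' channel extraction polarity, CLAHE, the denoising ensemble, the detector
#' choice and its parameters, anisotropic diffusion and thresholding options.
#'
#' @param polarity \code{"dark"} for real fundus images (vessels darker than
#'   background; the extracted channel is inverted) or \code{"bright"}.
#' @param clahe a \code{\link{ClaheParams}}.
#' @param denoise logical; \code{FALSE} bypasses the denoiser.
#' @param singleStage logical; \code{TRUE} stops each member after the
#'   LLMMSE pass (no Wiener refinement).
#' @param ensemble an \code{\link{EnsembleConfig}}.
#' @param detector \code{"frangi"} (eigenvalue-ratio filter) or
#'   \code{"multiscale"} (line detector).
#' @param frangi a \code{\link{FrangiParams}}.
#' @param line a \code{\link{LineDetectorParams}}.
#' @param diffusion a \code{\link{DiffusionParams}}.
#' @param autoLooks estimate the effective number of looks of the enhanced
#'   image with \code{\link{estimateLooks}} and propagate it to every
#'   ensemble member (default), keeping the pipeline free of an a-priori
#'   noise level; \code{FALSE} uses each member's configured \code{looks}.
#' @param diffusionStage \code{"pre"} (default) smooths the denoised image
#'   before detection, removing residual sub-kappa noise while preserving
#'   vessel edges; \code{"post"} smooths the vesselness map instead.
#' @param minComponent remove predicted components smaller than this many
#'   pixels; 0 disables (the default behavior).
#' @param fovThresholdFraction fraction of the Otsu level used when the
#'   field-of-view mask must be estimated from the image.
#' @return a \code{PipelineConfig} object.
#' @seealso \code{\link{segmentVessels}}
#' @export PipelineConfig
#' @exportClass PipelineConfig
#' @aliases PipelineConfig-class
setClass("PipelineConfig", representation(
    polarity = "character", clahe = "ClaheParams", denoise = "logical",
    singleStage = "logical", autoLooks = "logical",
    ensemble = "EnsembleConfig",
    detector = "character", frangi = "FrangiParams",
    line = "LineDetectorParams", diffusion = "DiffusionParams",
    diffusionStage = "character", minComponent = "integer",
    fovThresholdFraction = "numeric"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (!object@polarity %in% c("bright", "dark"))
        msg <- c(msg, "polarity must be 'bright' or 'dark'")
    if (!object@detector %in% c("frangi", "multiscale"))
        msg <- c(msg, "detector must be 'frangi' or 'multiscale'")
    if (!object@diffusionStage %in% c("post", "pre"))
        msg <- c(msg, "diffusionStage must be 'post' or 'pre'")
    if (object@minComponent < 0L) msg <- c(msg, "minComponent must be >= 0")
    if (object@fovThresholdFraction <= 0)
        msg <- c(msg, "fovThresholdFraction must be positive")
    if (length(msg)) msg else TRUE
})

PipelineConfig <- function(polarity = "dark", clahe = ClaheParams(),
                           denoise = TRUE, singleStage = FALSE,
                           autoLooks = TRUE, ensemble = defaultEnsemble(),
                           detector = "frangi", frangi = FrangiParams(),
                           line = LineDetectorParams(),
                           diffusion = DiffusionParams(),
                           diffusionStage = "pre", minComponent = 0L,
                           fovThresholdFraction = 0.5) {
    new("PipelineConfig", polarity = polarity, clahe = clahe,
        denoise = denoise, singleStage = singleStage,
        autoLooks = autoLooks, ensemble = ensemble,
        detector = detector, frangi = frangi, line = line,
        diffusion = diffusion, diffusionStage = diffusionStage,
        minComponent = as.integer(minComponent),
        fovThresholdFraction = as.numeric(fovThresholdFraction))
}

#' Segmentation result
#'
#' Holds the binary vessel mask, the (diffusion-smoothed) vesselness map the
#' threshold was applied to, the converged ISODATA threshold and a
#' machine-readable run log of every stage's parameters.
#'
#' @seealso \code{\link{segmentVessels}}, \code{\link{vesselMask}},
#'   \code{\link{vesselness}}, \code{\link{thresholdValue}},
#'   \code{\link{runLog}}
#' @exportClass SegmentationResult
#' @aliases SegmentationResult-class
setClass("SegmentationResult", representation(
    mask = "matrix", vesselness = "matrix", fov = "matrix",
    threshold = "numeric", log = "list"))

# -- show methods ------------------------------------------------------------

setMethod("show", "DenoiserParams", function(object) {
    cat(sprintf(
        "DenoiserParams: block %d, search %d, step %d, maxGroup %d, L %.3g, gamma %.3g, %s x%d levels, %s stack\n",
        object@blockSize, object@searchWindow, object@step, object@maxGroup,
        object@looks, object@gamma, object@wavelet, object@levels,
        object@groupTransform))
})

setMethod("show", "EnsembleConfig", function(object) {
    cat(sprintf("EnsembleConfig: %d member(s), combine = %s\n",
                length(object@members), object@combine))
    for (m in object@members)
        cat(sprintf("  block %d, search %d\n", m@blockSize, m@searchWindow))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %dx%d, background %.2f, %d vessel segment(s), %s vessels, FOV %.2f, seed %d\n",
        object@width, object@height, object@backgroundLevel,
        length(object@vessels), object@polarity, object@fovRadiusFraction,
        object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(
        "PipelineConfig: polarity %s | CLAHE %dx%d clip %.2g | denoise %s (%d member(s)%s) | detector %s | diffusion %d it (%s) | ISODATA threshold\n",
        object@polarity, object@clahe@tiles[1], object@clahe@tiles[2],
        object@clahe@clipLimit, if (object@denoise) "on" else "off",
        length(object@ensemble@members),
        if (object@singleStage) ", single stage" else "",
        object@detector, object@diffusion@iterations, object@diffusionStage))
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf(
        "SegmentationResult: %dx%d, %d vessel pixels (%.1f%% of FOV), threshold %.4f\n",
        nrow(object@mask), ncol(object@mask), sum(object@mask),
        100 * sum(object@mask) / max(1, sum(object@fov)), object@threshold))
})
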