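# YAML (de)serialization of configurations.  The YAML layout mirrors the
# pipeline stages: preprocess / denoiser / ensemble / detector / postprocess.

pipeline_to_list <- function(cfg) {
    list(
        preprocess = list(
            polarity = cfg@polarity,
            tiles = as.integer(cfg@clahe@tiles),
            clip_limit = cfg@clahe@clipLimit,
            n_bins = cfg@clahe@nBins,
            fov_threshold_fraction = cfg@fovThresholdFraction),
        denoiser = list(enabled = cfg@denoise,
                        single_stage = cfg@singleStage,
                        auto_looks = cfg@autoLooks),
        ensemble = list(
            combine = cfg@ensemble@combine,
            weights = as.numeric(cfg@ensemble@weights),
            members = lapply(cfg@ensemble@members, function(m) list(
                block_size = m@blockSize, search_window = m@searchWindow,
                step = m@step, max_group = m@maxGroup, looks = m@looks,
                gamma = m@gamma, wavelet = m@wavelet, levels = m@levels,
                group_transform = m@groupTransform))),
        detector = list(
            method = cfg@detector,
            frangi = list(scales = cfg@frangi@scales, tau = cfg@frangi@tau,
                          alpha = cfg@frangi@alpha, kappa = cfg@frangi@kappa),
            multiscale = list(sigma_v = cfg@line@sigmaV,
                              ratios = cfg@line@ratios,
                              orientations = cfg@line@orientations,
                              alpha = cfg@line@alpha, beta = cfg@line@beta)),
        postprocess = list(
            iterations = cfg@diffusion@iterations,
            kappa = cfg@diffusion@kappa, dt = cfg@diffusion@dt,
            conduction = cfg@diffusion@conduction,
            diffusion_stage = cfg@diffusionStage,
            min_component = cfg@minComponent))
}

pick <- function(lst, key, default) {
    if (!is.null(lst[[key]])) lst[[key]] else default
}

pipeline_from_list <- function(lst) {
    d <- PipelineConfig()  # defaults
    pre <- pick(lst, "preprocess", list())
    den <- pick(lst, "denoiser", list())
    ens <- pick(lst, "ensemble", list())
    det <- pick(lst, "detector", list())
    pos <- pick(lst, "postprocess", list())
    members <- if (!is.null(ens$members)) {
        lapply(ens$members, function(m) DenoiserParams(
            blockSize = pick(m, "block_size", 8L),
            searchWindow = pick(m, "search_window", 39L),
            step = pick(m, "step", 3L),
            maxGroup = pick(m, "max_group", 16L),
            looks = pick(m, "looks", 4),
            gamma = pick(m, "gamma", 4),
            wavelet = pick(m, "wavelet", "daub8"),
            levels = pick(m, "levels", 2L),
            groupTransform = pick(m, "group_transform", "haar")))
    } else d@ensemble@members
    PipelineConfig(
        polarity = pick(pre, "polarity", d@polarity),
        clahe = ClaheParams(
            tiles = pick(pre, "tiles", d@clahe@tiles),
            clipLimit = pick(pre, "clip_limit", d@clahe@clipLimit),
            nBins = pick(pre, "n_bins", d@clahe@nBins)),
        fovThresholdFraction = pick(pre, "fov_threshold_fraction",
                                    d@fovThresholdFraction),
        denoise = pick(den, "enabled", d@denoise),
        singleStage = pick(den, "single_stage", d@singleStage),
        autoLooks = pick(den, "auto_looks", d@autoLooks),
        ensemble = EnsembleConfig(
            members = members,
            combine = pick(ens, "combine", d@ensemble@combine),
            weights = pick(ens, "weights", d@ensemble@weights)),
        detector = pick(det, "method", d@detector),
        frangi = FrangiParams(
            scales = pick(det$frangi, "scales", d@frangi@scales),
            tau = pick(det$frangi, "tau", d@frangi@tau),
            alpha = pick(det$frangi, "alpha", d@frangi@alpha),
            kappa = pick(det$frangi, "kappa", d@frangi@kappa)),
        line = LineDetectorParams(
            sigmaV = pick(det$multiscale, "sigma_v", d@line@sigmaV),
            ratios = pick(det$multiscale, "ratios", d@line@ratios),
            orientations = pick(det$multiscale, "orientations",
                                d@line@orientations),
            alpha = pick(det$multiscale, "alpha", d@line@alpha),
            beta = pick(det$multiscale, "beta", d@line@beta)),
        diffusion = DiffusionParams(
            iterations = pick(pos, "iterations", d@diffusion@iterations),
            kappa = pick(pos, "kappa", d@diffusion@kappa),
            dt = pick(pos, "dt", d@diffusion@dt),
            conduction = pick(pos, "conduction", d@diffusion@conduction)),
        diffusionStage = pick(pos, "diffusion_stage", d@diffusionStage),
        minComponent = pick(pos, "min_component", d@minComponent))
}

#' Read / write a pipeline configuration as YAML
#'
#' Missing keys fall back to the package defaults, so a YAML file only needs
#' the values it overrides.
#'
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: a \code{\link{PipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
    pipeline_from_list(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param cfg a \code{\link{PipelineConfig}} to serialize.
#' @export
writePipelineConfig <- function(cfg, path) {
    validObject(cfg)
    yaml::write_yaml(pipeline_to_list(cfg), path)
    invisible(path)
}

#' Read / write a phantom specification as YAML
#'
#' @param path YAML file path.
#' @return \code{readPhantomSpec}: a \code{\link{PhantomSpec}} plus the
#'   \code{\link{NoiseSpec}} under its \code{noise} attribute when present.
#' @export
readPhantomSpec <- function(path) {
    lst <- yaml::read_yaml(path)
    vessels <- lapply(pick(lst, "vessels", list()), function(v) {
        out <- list(from = as.numeric(v$from), to = as.numeric(v$to),
                    amp = v$amp, sigma = v$sigma)
        if (!is.null(v$ctrl)) out$ctrl <- as.numeric(v$ctrl)
        out
    })
    spec <- PhantomSpec(
        width = pick(lst, "width", 256L),
        height = pick(lst, "height", 256L),
        backgroundLevel = pick(lst, "background_level", 0.4),
        vessels = vessels,
        polarity = pick(lst, "polarity", "dark"),
        fovRadiusFraction = pick(lst, "fov_radius_fraction", 0.94),
        seed = pick(lst, "seed", 1L))
    noise <- lst$noise
    if (!is.null(noise)) {
        attr(spec, "noise") <- NoiseSpec(
            looks = pick(noise, "looks", 4),
            additiveSigma = pick(noise, "additive_sigma", 0),
            seed = pick(noise, "seed", spec@seed))
    }
    spec
}

#' @rdname readPhantomSpec
#' @param spec a \code{\link{PhantomSpec}}.
#' @param noise optional \code{\link{NoiseSpec}} stored alongside.
#' @export
writePhantomSpec <- function(spec, path, noise = NULL) {
    validObject(spec)
    lst <- list(width = spec@width, height = spec@height,
                background_level = spec@backgroundLevel,
                polarity = spec@polarity,
                fov_radius_fraction = spec@fovRadiusFraction,
                seed = spec@seed,
                vessels = lapply(spec@vessels, function(v) {
                    out <- list(from = as.numeric(v$from),
                                to = as.numeric(v$to),
                                amp = v$amp, sigma = v$sigma)
                    if (!is.null(v$ctrl)) out$ctrl <- as.numeric(v$ctrl)
                    out
                }))
    if (!is.null(noise))
        lst$noise <- list(looks = noise@looks,
                          additive_sigma = noise@additiveSigma,
                          seed = noise@seed)
    yaml::write_yaml(lst, path)
    invisible(path)
}
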