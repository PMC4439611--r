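#' Pipeline configuration
#'
#' Collects every stage's parameter block plus the segmentation method and
#' stage toggles. Stage order is fixed: SRAD denoising, homomorphic
#' correction, circular-Hough ROI detection, segmentation (one of
#' `acwe`, `spf`, `gmm`, `fcm`), anatomical postprocessing, evaluation.
#' Toggles only remove stages, never reorder them.
#'
#' @param method `"acwe"`, `"spf"`, `"gmm"`, or `"fcm"`.
#' @param srad an [srad_params()].
#' @param homomorphic a [homomorphic_params()].
#' @param hough list `(r_min, r_max, enlargement_factor, min_support)`;
#'   `NULL` entries use the detector defaults.
#' @param acwe an [acwe_params()].
#' @param spf an [spf_params()].
#' @param seed RNG seed for the clustering initializations.
#' @param element_radius,sector_deg postprocessing knobs (see
#'   [suppress_attachments()] and [detect_side()]).
#' @param skip_preprocess,skip_postprocess stage toggles.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = "acwe",
                            srad = srad_params(),
                            homomorphic = homomorphic_params(),
                            hough = list(r_min = NULL, r_max = NULL,
                                         enlargement_factor = 1.2,
                                         min_support = 0.25),
                            acwe = acwe_params(),
                            spf = spf_params(),
                            seed = 1L,
                            element_radius = 4L,
                            sector_deg = 90,
                            skip_preprocess = FALSE,
                            skip_postprocess = FALSE) {
  if (!method %in% c("acwe", "spf", "gmm", "fcm"))
    stop("pipeline_config: unknown method '", method, "'")
  structure(list(method = method, srad = srad, homomorphic = homomorphic,
                 hough = hough, acwe = acwe, spf = spf, seed = as.integer(seed),
                 element_radius = as.integer(element_radius),
                 sector_deg = sector_deg,
                 skip_preprocess = isTRUE(skip_preprocess),
                 skip_postprocess = isTRUE(skip_postprocess)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] blocks, e.g.
#' `method: acwe`, `srad: {n_iters: 50, dt: 0.05}`, `acwe: {mu: 0.2}`.
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("method", "srad", "homomorphic", "hough", "acwe", "spf", "seed",
             "element_radius", "sector_deg", "skip_preprocess",
             "skip_postprocess")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("read_pipeline_config: unknown keys: ",
                        paste(bad, collapse = ", "))
  args <- list()
  for (nm in c("method", "seed", "element_radius", "sector_deg",
               "skip_preprocess", "skip_postprocess"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$srad)) args$srad <- do.call(srad_params, y$srad)
  if (!is.null(y$homomorphic))
    args$homomorphic <- do.call(homomorphic_params, y$homomorphic)
  if (!is.null(y$acwe)) args$acwe <- do.call(acwe_params, y$acwe)
  if (!is.null(y$spf)) args$spf <- do.call(spf_params, y$spf)
  if (!is.null(y$hough)) {
    h <- pipeline_config()$hough
    h[names(y$hough)] <- y$hough
    args$hough <- h
  }
  do.call(pipeline_config, args)
}

#' Run the full segmentation pipeline on one slice
#'
#' Executes (unless toggled off) SRAD, homomorphic correction, Hough ROI
#' detection, the configured segmentation method, and anatomical
#' postprocessing, in that fixed order. If a reference mask is supplied,
#' Dice is recorded both before and after postprocessing. Deterministic
#' for fixed configuration and seeds.
#'
#' @param image an [image2d()].
#' @param config a [pipeline_config()].
#' @param truth optional reference [binary_mask()].
#' @param verbose print per-stage progress to stderr.
#' @return list with `result` (final [segmentation_result()], Dice filled
#'   in when truth given), `raw_result` (pre-postprocessing), `roi`,
#'   `side`, `preprocessed` ([image2d()]), `record` (one-row data frame
#'   with `method`, `dice_pre`, `dice_post`, `iterations`).
#' @export
run_pipeline <- function(image, config = pipeline_config(), truth = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(image, "image2d"), inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    say("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  pre <- image
  if (!config$skip_preprocess) {
    pre <- stage("srad", srad(pre, config$srad))
    pre <- stage("homomorphic", homomorphic_correct(pre, config$homomorphic))
  }
  roi <- stage("hough", do.call(detect_humeral_circle,
                                c(list(image = pre), config$hough)))
  side <- detect_side(image, config$sector_deg)
  raw <- stage(config$method, switch(config$method,
    acwe = acwe_segment(pre, roi, config$acwe),
    spf = spf_segment(pre, roi, config$spf),
    gmm = gmm_segment(pre, roi, seed = config$seed),
    fcm = fcm_segment(pre, roi, seed = config$seed)))
  dice_pre <- if (!is.null(truth)) dice(raw$mask, truth) else NA_real_
  raw$dice <- dice_pre
  final <- raw
  if (!config$skip_postprocess)
    final <- stage("postprocess",
                   postprocess_result(raw, roi, side, config$element_radius))
  dice_post <- if (!is.null(truth)) dice(final$mask, truth) else NA_real_
  final$dice <- dice_post
  list(result = final, raw_result = raw, roi = roi, side = side,
       preprocessed = pre,
       record = data.frame(method = config$method,
                           dice_pre = dice_pre, dice_post = dice_post,
                           iterations = raw$iterations_run,
                           stringsAsFactors = FALSE))
}
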