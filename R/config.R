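#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its documented
#' default: `sliver_min_size` (27 voxels, one 3x3x3 cell) for residual-region
#' filtering, `angularity_threshold` (1.0, the hemispherical-bump sharpness),
#' `posterior_fraction` (2/3 of the maximum section area),
#' `posterior_height_cap` (100 voxels), `mesh_smooth_iter` (20 Taubin
#' iterations for surface meshes), the GA settings ([ga_config()]), the seed
#' and the log level. Round-trips through YAML via [write_config()] /
#' [read_config()].
#'
#' @param ... overrides of the defaults.
#' @return named list of class `grading_config`.
#' @export
grading_config <- function(...) {
  cfg <- list(
    sliver_min_size = 27L,
    angularity_threshold = 1.0,
    posterior_fraction = 2 / 3,
    posterior_height_cap = 100L,
    mesh_smooth_iter = 100L,
    gray_levels = 16L,
    ga = ga_config(),
    seed = 1L,
    log_level = "info")
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(names(dots) %in% names(cfg)))
    if (!is.null(dots$ga) && !inherits(dots$ga, "ga_config")) {
      dots$ga <- do.call(ga_config, dots$ga)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "grading_config")
}

#' Genetic-algorithm settings
#'
#' Fitness weights are fixed at 0.8 (sensitivity x specificity product) and
#' 0.2 (reciprocal of the selected-feature count); the remaining knobs are
#' conventional defaults: population 50, 100 generations, one-point
#' crossover at rate 0.8, bit-flip mutation at rate 0.02, elitism 1, inner
#' 5-fold CV for the fitness evaluation, log2(C) in \[-5, 15\] and
#' log2(gamma) in \[-15, 3\].
#'
#' @param ... overrides of the defaults.
#' @return named list of class `ga_config`.
#' @export
ga_config <- function(...) {
  cfg <- list(
    population = 50L, generations = 100L,
    crossover_rate = 0.8, mutation_rate = 0.02,
    elitism = 1L, inner_folds = 5L,
    w_perf = 0.8, w_parsimony = 0.2,
    log2C_range = c(-5, 15), log2gamma_range = c(-15, 3),
    sigma_mut = 1.0)
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(names(dots) %in% names(cfg)))
    cfg[names(dots)] <- dots
  }
  cfg$log2C_range <- as.numeric(unlist(cfg$log2C_range))
  cfg$log2gamma_range <- as.numeric(unlist(cfg$log2gamma_range))
  stopifnot(cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1)
  structure(cfg, class = "ga_config")
}

#' @rdname grading_config
#' @param config a `grading_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$ga <- unclass(x$ga)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname grading_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  ga <- x$ga
  x$ga <- NULL
  cfg <- do.call(grading_config, x)
  if (!is.null(ga)) cfg$ga <- do.call(ga_config, ga)
  cfg
}
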