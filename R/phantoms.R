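## Synthetic 3-D ultrasound-like phantoms: an ellipsoidal hypoechoic lesion
## (optionally decorated with surface protrusions) embedded in correlated
## speckle-like noise, with a controllable additive gray shift in the
## posterior prism (positive = enhancement, negative = shadowing). The
## generator emulates only the second-order gray statistics and shapes the
## features respond to; it is not a physical scattering simulation.

#' Specify a phantom case
#'
#' Defaults describe a hypoechoic lesion (mean gray 60 on a 120 background)
#' with speckle of SD 20 and ~1.5-voxel correlation length, at the 0.2 mm
#' isotropic resolution of the target acquisition, inside a 64^3 grid with
#' room for a posterior region.
#'
#' @param dim grid shape (3 integers).
#' @param spacing voxel spacing mm.
#' @param semi_axes lesion semi-axes in voxels (sorted or not).
#' @param center lesion center in voxel coordinates (default: lateral
#'   center, upper third of the depth axis).
#' @param n_protrusions number of spherical surface bumps.
#' @param protrusion_radius bump radius in voxels.
#' @param protrusion_length radial offset of the bump center from the
#'   lesion surface, in voxels (larger = spikier).
#' @param lesion_mean,background_mean mean gray levels.
#' @param speckle_sd speckle standard deviation (gray levels); 0 disables
#'   noise.
#' @param correlation_length Gaussian correlation length of the speckle in
#'   voxels.
#' @param posterior_shift additive gray shift in the posterior prism.
#' @param seed RNG seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64L, 64L, 64L), spacing = c(0.2, 0.2, 0.2),
                         semi_axes = c(14, 11, 9), center = NULL,
                         n_protrusions = 0L, protrusion_radius = 4,
                         protrusion_length = 2,
                         lesion_mean = 60, background_mean = 120,
                         speckle_sd = 20, correlation_length = 1.5,
                         posterior_shift = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (is.null(center)) center <- c(dim[1] / 3, dim[2] / 2, dim[3] / 2)
  spec <- list(dim = dim, spacing = as.numeric(spacing),
               semi_axes = as.numeric(semi_axes), center = as.numeric(center),
               n_protrusions = as.integer(n_protrusions),
               protrusion_radius = protrusion_radius,
               protrusion_length = protrusion_length,
               lesion_mean = lesion_mean, background_mean = background_mean,
               speckle_sd = speckle_sd,
               correlation_length = correlation_length,
               posterior_shift = posterior_shift, seed = as.integer(seed))
  stopifnot(all(spec$semi_axes > 0), all(spec$spacing > 0),
            spec$lesion_mean >= 0, spec$lesion_mean <= 255,
            spec$background_mean >= 0, spec$background_mean <= 255)
  if (spec$center[1] + max(spec$semi_axes) >= dim[1] - 2) {
    stop("lesion too deep: no room for a posterior region", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

## Rasterize an axis-aligned ellipsoid plus optional protrusion spheres.
phantom_mask <- function(spec) {
  d <- spec$dim
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  u <- sweep(as.matrix(g), 2, spec$center)
  r2 <- rowSums(sweep(u, 2, spec$semi_axes, "/")^2)
  mask <- array(r2 <= 1, d)
  if (spec$n_protrusions > 0) {
    # deterministic, well-separated directions on the sphere
    dirs <- protrusion_directions(spec$n_protrusions)
    for (i in seq_len(spec$n_protrusions)) {
      v <- dirs[i, ]
      # point on the ellipsoid surface along direction v, pushed outward
      t_surf <- 1 / sqrt(sum((v / spec$semi_axes)^2))
      ctr <- spec$center + v * (t_surf + spec$protrusion_length)
      d2 <- rowSums(sweep(as.matrix(g), 2, ctr)^2)
      mask <- mask | array(d2 <= spec$protrusion_radius^2, d)
    }
  }
  mask
}

## n approximately equidistributed unit directions (Fibonacci sphere),
## avoiding the straight-down pole so protrusions do not merge with the
## posterior prism construction.
protrusion_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n) * 0.9 + 0.05 * pi
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * cos(theta), sin(phi) * sin(theta))
}

#' Generate a phantom case
#'
#' Builds the lesion mask and the gray-level volume: correlated Gaussian
#' speckle (Gaussian-filtered white noise rescaled to the requested SD)
#' around piecewise means (hypoechoic lesion, brighter background), plus
#' the posterior gray shift applied inside the posterior prism constructed
#' by [build_posterior()]. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([voxel_volume()]), `mask` ([lesion_mask()]),
#'   and `truth` (the spec plus derived ground-truth fields).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  mask <- phantom_mask(spec)
  base <- array(spec$background_mean, d)
  base[mask] <- spec$lesion_mean
  if (spec$speckle_sd > 0) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (spec$correlation_length > 0) {
      noise <- smooth_gauss3(noise, spec$correlation_length)
      noise <- noise / sqrt(mean(noise^2))
    }
    base <- base + spec$speckle_sd * noise
  }
  lm <- lesion_mask(mask, spec$spacing)
  post <- tryCatch(build_posterior(lm), error = function(e) NULL)
  if (!is.null(post) && spec$posterior_shift != 0) {
    base[post$mask] <- base[post$mask] + spec$posterior_shift
  }
  vol <- voxel_volume(pmin(pmax(base, 0), 255), spec$spacing, clip = TRUE)
  truth <- c(unclass(spec),
             list(n_lesion_voxels = sum(lm$data),
                  posterior_voxels = if (is.null(post)) 0L else sum(post$mask)))
  list(volume = vol, mask = lm, truth = truth)
}

#' Generate a labelled phantom cohort
#'
#' Draws per-case phantom specs for `n_low` low-grade and `n_high`
#' high-grade cases. The `effect` profile states how the high-grade
#' distribution is shifted, in the directions reported for real cohorts:
#' stronger posterior enhancement, shorter speckle correlation (lower GLCM
#' correlation), and optionally more protrusions. `effect = "null"` makes
#' the two groups identically distributed; `effect = "strong"` separates
#' them by about two within-group SDs on the affected features.
#'
#' @param n_low,n_high class sizes.
#' @param effect `"null"`, `"strong"`, or a named list with per-class means
#'   `posterior_shift = c(low, high)`, `correlation_length = c(low, high)`,
#'   `n_protrusions = c(low, high)`.
#' @param seed cohort seed; per-case seeds are derived from it.
#' @param dim,spacing grid geometry shared by all cases.
#' @param semi_axes_range range (voxels) the per-case lesion semi-axes are
#'   drawn from.
#' @return list of class `phantom_cohort`: `cases` (list of specs),
#'   `labels` (factor), `manifest` (data frame: case_id, label, seed).
#' @export
generate_cohort <- function(n_low, n_high, effect = "strong", seed = 1L,
                            dim = c(64L, 48L, 48L),
                            spacing = c(0.2, 0.2, 0.2),
                            semi_axes_range = c(7, 12)) {
  stopifnot(n_low > 0, n_high > 0)
  if (is.character(effect)) {
    effect <- switch(match.arg(effect, c("null", "strong")),
      null = list(posterior_shift = c(30, 30),
                  correlation_length = c(1.5, 1.5),
                  n_protrusions = c(2L, 2L)),
      strong = list(posterior_shift = c(10, 70),
                    correlation_length = c(2.2, 1.0),
                    n_protrusions = c(1L, 4L)))
  }
  set.seed(seed)
  n <- n_low + n_high
  labels <- factor(rep(c("low", "high"), c(n_low, n_high)),
                   levels = grade_levels)
  case_seeds <- sample.int(.Machine$integer.max, n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    g <- if (labels[i] == "high") 2L else 1L
    ax <- sort(stats::runif(3, semi_axes_range[1], semi_axes_range[2]),
               decreasing = TRUE)
    cases[[i]] <- phantom_spec(
      dim = dim, spacing = spacing, semi_axes = ax,
      n_protrusions = effect$n_protrusions[g],
      posterior_shift = effect$posterior_shift[g] + stats::rnorm(1, 0, 10),
      correlation_length = max(0.4,
        effect$correlation_length[g] + stats::rnorm(1, 0, 0.2)),
      seed = case_seeds[i])
  }
  manifest <- data.frame(case_id = sprintf("case%03d", seq_len(n)),
                         label = as.character(labels), seed = case_seeds,
                         stringsAsFactors = FALSE)
  structure(list(cases = cases, labels = labels, manifest = manifest,
                 effect = effect, seed = seed),
            class = "phantom_cohort")
}

#' Extract the feature table of a phantom cohort
#'
#' Generates each case's volume/mask and runs [extract_features()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [grading_config()].
#' @return data frame: `case_id`, the 44 features, `label`.
#' @export
cohort_features <- function(cohort, config = grading_config()) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  rows <- lapply(cohort$cases, function(spec) {
    ph <- generate_phantom(spec)
    extract_features(ph$volume, ph$mask, config)
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(data.frame(case_id = cohort$manifest$case_id,
                   stringsAsFactors = FALSE),
        tab,
        data.frame(label = cohort$manifest$label, stringsAsFactors = FALSE))
}
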