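## Posterior acoustic region and features. The posterior region is the
## prism beneath the lesion along the beam axis (axis 1, larger index =
## deeper): its footprint is the lesion's maximum C-view section shrunk to
## two-thirds of its area via the Euclidean distance transform (avoiding the
## edge-shadowing rim), and its height equals the lesion height, capped at
## 100 voxels and clipped to the volume.

#' Maximum C-view section of a lesion
#'
#' Scans constant-depth (axis-1) slices and returns the one with maximal
#' foreground area; ties break toward the smaller depth index.
#'
#' @param mask a [lesion_mask()] or logical array.
#' @return list with `depth` (slice index), `section` (2-D logical matrix),
#'   `area` (voxels).
#' @export
max_section <- function(mask) {
  if (inherits(mask, "lesion_mask")) mask <- mask$data
  areas <- apply(mask, 1, sum)
  k <- which.max(areas)           # first maximum = shallowest
  list(depth = k, section = mask[k, , ], area = areas[k])
}

#' Shrink a 2-D section to a target area fraction
#'
#' Thresholds the Euclidean distance transform of the section at the
#' smallest level whose superlevel set has area at most
#' `target * area(section)`: the rule is met from below, never exceeded,
#' and the result is a concentric subset of the input.
#'
#' @param section 2-D logical matrix.
#' @param target area fraction in (0, 1\]; default 2/3.
#' @return 2-D logical matrix (subset of `section`).
#' @export
shrink_section <- function(section, target = 2 / 3) {
  stopifnot(length(dim(section)) == 2)
  if (target <= 0 || target > 1) stop("target fraction must be in (0, 1]",
                                      call. = FALSE)
  section <- section > 0
  a0 <- sum(section)
  if (a0 == 0) stop("empty section", call. = FALSE)
  if (target == 1) return(section)
  ij <- which(section, arr.ind = TRUE)
  degenerate <- diff(range(ij[, 1])) == 0 || diff(range(ij[, 2])) == 0
  dm <- if (degenerate) distmap_line(section) else distmap2(section)
  lv <- sort(unique(dm[section]))
  goal <- target * a0
  for (t in lv) {
    if (sum(dm >= t) <= goal) return(dm >= t)
  }
  # only the deepest layer remains
  dm >= max(lv)
}

#' Build the posterior acoustic region
#'
#' Extrudes the shrunken maximum-section footprint along increasing depth,
#' starting one voxel below the lesion's deepest foreground index, for
#' `min(lesion height, height_cap)` slices, clipped to the volume; voxels
#' overlapping the lesion are excluded.
#'
#' @param mask a [lesion_mask()].
#' @param target footprint area fraction (default 2/3).
#' @param height_cap maximum height in voxels (default 100).
#' @return object of class `posterior_region`: list with `mask` (logical
#'   array, same shape), `section_area_voxels`, `height_voxels`.
#' @export
build_posterior <- function(mask, target = 2 / 3, height_cap = 100L) {
  m <- mask$data
  d <- dim(m)
  zs <- which(apply(m, 1, any))
  z0 <- min(zs); z1 <- max(zs)
  height <- min(z1 - z0 + 1L, as.integer(height_cap))
  ms <- max_section(m)
  foot <- shrink_section(ms$section, target)
  if (z1 + 1L > d[1]) {
    stop("lesion touches the deepest slice: empty posterior region",
         call. = FALSE)
  }
  zrange <- (z1 + 1L):min(z1 + height, d[1])
  post <- array(FALSE, d)
  post[zrange, , ] <- rep(foot, each = length(zrange))
  post <- post & !m
  if (!any(post)) stop("posterior region is empty after clipping",
                       call. = FALSE)
  structure(list(mask = post, section_area_voxels = sum(foot),
                 height_voxels = length(zrange)),
            class = "posterior_region")
}

#' @export
print.posterior_region <- function(x, ...) {
  cat(sprintf("<posterior_region> footprint %d voxels, height %d, total %d\n",
              x$section_area_voxels, x$height_voxels, sum(x$mask)))
  invisible(x)
}

#' The five posterior acoustic features
#'
#' With mean/population-SD gray level `(mu_p, sigma_p)` over the posterior
#' region and `(mu_t, sigma_t)` over the lesion: `P_std = sigma_p`,
#' `P_Rm = mu_p / mu_t`, `P_Rstd = sigma_p / sigma_t`,
#' `P_Sm = mu_p - mu_t`, `P_Sstd = sigma_p - sigma_t`. Ratios with a zero
#' denominator are returned as `NA` with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [lesion_mask()].
#' @param post a [build_posterior()] result (built with defaults if omitted).
#' @return named numeric vector `c(P_std, P_Rstd, P_Sstd, P_Sm, P_Rm)`
#'   (report order).
#' @export
posterior_features <- function(volume, mask, post = NULL) {
  if (is.null(post)) post <- build_posterior(mask)
  g <- volume$data
  gp <- as.numeric(g[post$mask])
  gt <- as.numeric(g[mask$data])
  mu_p <- mean(gp); mu_t <- mean(gt)
  sd_p <- sqrt(mean((gp - mu_p)^2))
  sd_t <- sqrt(mean((gt - mu_t)^2))
  rm_ <- if (mu_t == 0) {
    warning("all-black lesion: P_Rm undefined", call. = FALSE); NA_real_
  } else mu_p / mu_t
  rstd <- if (sd_t == 0) {
    warning("constant-gray lesion: P_Rstd undefined", call. = FALSE); NA_real_
  } else sd_p / sd_t
  c(P_std = sd_p, P_Rstd = rstd, P_Sstd = sd_p - sd_t,
    P_Sm = mu_p - mu_t, P_Rm = rm_)
}
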