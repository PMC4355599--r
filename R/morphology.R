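## Six morphological descriptors of the segmented lesion: physical volume
## and surface area, two compactness measures (sphere- and cube-normalized),
## and radius statistics from the center of mass to the surface voxels.

#' Lesion volume in mm^3
#'
#' Voxel count times the voxel volume (product of the mm spacings).
#'
#' @param mask a [lesion_mask()] or logical array.
#' @param spacing voxel spacing in mm (taken from the mask if omitted).
#' @return volume in mm^3.
#' @export
lesion_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  sum(mask) * prod(spacing)
}

#' Lesion surface area in mm^2
#'
#' Area of the smoothed 0.5-level isosurface mesh (see [surface_mesh()]),
#' honouring anisotropic spacing. Masks touching the grid border are padded
#' by one background voxel inside [surface_mesh()], so the surface is always
#' closed.
#'
#' @inheritParams lesion_volume
#' @param smooth_iter Taubin smoothing iterations passed to [surface_mesh()].
#' @return area in mm^2.
#' @export
surface_area <- function(mask, spacing = NULL, smooth_iter = 100L) {
  mesh_area(surface_mesh(mask, spacing, smooth_iter = smooth_iter))
}

#' Classical (sphere-normalized) compactness
#'
#' `36 * pi * V^2 / A^3`: 1 for a continuum sphere, smaller for any other
#' shape. Measures similarity between the lesion and its optimally fitted
#' sphere.
#'
#' @param volume_mm3 lesion volume (mm^3).
#' @param area_mm2 lesion surface area (mm^2).
#' @return dimensionless compactness.
#' @export
classical_compactness <- function(volume_mm3, area_mm2) {
  stopifnot(volume_mm3 > 0, area_mm2 > 0)
  36 * pi * volume_mm3^2 / area_mm2^3
}

#' Discrete (cube-normalized) compactness
#'
#' Bribiesca's contact-surface measure on the voxel lattice: with `n`
#' foreground voxels and `F` exposed voxel faces, the number of shared
#' (contact) faces is `A_c = (6n - F) / 2`, and the maximum for `n` voxels
#' is `A_c_max = 3 (n - n^(2/3))`. The feature is `A_c / A_c_max`, clipped
#' to \[0, 1\]; solid cubes score 1. A single voxel is defined as 1.
#'
#' @param mask a [lesion_mask()] or logical array.
#' @return dimensionless compactness in \[0, 1\].
#' @export
discrete_compactness <- function(mask) {
  if (inherits(mask, "lesion_mask")) mask <- mask$data
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  if (n == 1) {
    message("single-voxel mask: discrete compactness defined as 1")
    return(1)
  }
  ac <- contact_faces(mask)
  ac_max <- 3 * (n - n^(2 / 3))
  min(max(ac / ac_max, 0), 1)
}

## Number of voxel faces shared by two foreground voxels (6-adjacency).
contact_faces <- function(mask) {
  d <- dim(mask)
  ac <- 0
  ac <- ac + sum(mask[-d[1], , , drop = FALSE] & mask[-1, , , drop = FALSE])
  ac <- ac + sum(mask[, -d[2], , drop = FALSE] & mask[, -1, , drop = FALSE])
  ac <- ac + sum(mask[, , -d[3], drop = FALSE] & mask[, , -1, drop = FALSE])
  ac
}

#' Radius statistics of the lesion surface
#'
#' Distances (mm) from the lesion's center of mass to every surface voxel
#' (foreground voxel with at least one of its six face-neighbours in the
#' background). Returns the mean radius and the population standard
#' deviation, which capture size and surface irregularity respectively.
#' A single-voxel mask returns `c(0, 0)` by convention.
#'
#' @inheritParams lesion_volume
#' @return named numeric vector `c(Rm, Rstd)` in mm.
#' @export
radius_stats <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  if (n == 1) return(c(Rm = 0, Rstd = 0))
  surf <- surface_voxels(mask)
  ai <- arrayInd(which(mask), dim(mask))
  com <- colMeans(ai) * spacing
  si <- arrayInd(which(surf), dim(mask))
  pts <- sweep(si, 2, as.numeric(spacing), "*")
  dists <- sqrt(rowSums(sweep(pts, 2, com)^2))
  m <- mean(dists)
  c(Rm = m, Rstd = sqrt(mean((dists - m)^2)))
}

## Foreground voxels 6-adjacent to background (grid border = background).
surface_voxels <- function(mask) {
  p <- pad3(mask, FALSE, 1L)
  d <- dim(p)
  core <- p[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  nb <- p[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE] &
    p[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE] &
    p[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1), drop = FALSE] &
    p[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1), drop = FALSE] &
    p[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2), drop = FALSE] &
    p[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3], drop = FALSE]
  core & !nb
}

#' The six morphological features
#'
#' @param mask a [lesion_mask()].
#' @param smooth_iter surface-mesh smoothing iterations (see [surface_mesh()]).
#' @return named numeric vector `c(M_V, M_A, M_Rm, M_Rstd, M_Cc, M_Cd)`
#'   (report order).
#' @export
morphology_features <- function(mask, smooth_iter = 100L) {
  v <- lesion_volume(mask)
  a <- surface_area(mask, smooth_iter = smooth_iter)
  rs <- radius_stats(mask)
  c(M_V = v, M_A = a, M_Rm = unname(rs["Rm"]), M_Rstd = unname(rs["Rstd"]),
    M_Cc = classical_compactness(v, a), M_Cd = discrete_compactness(mask))
}
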