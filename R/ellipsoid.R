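## Ellipsoid fitting and residual-region analysis. The optimally fitted
## ellipsoid is moment-matched: its center is the lesion's center of mass
## and its axes come from the eigendecomposition of the voxel-coordinate
## covariance, using the solid-ellipsoid relation a_i = sqrt(5 * lambda_i).
## The fitted ellipsoid is the baseline against which shape irregularity is
## counted: connected residual regions of lesion-minus-ellipsoid (outside)
## and ellipsoid-minus-lesion (inside), with small discretization slivers
## removed, plus "angularity" flags for sharply protruding regions.

#' Fit an ellipsoid to a lesion mask by moment matching
#'
#' @param mask a [lesion_mask()] or logical array.
#' @param spacing voxel spacing in mm (taken from the mask if omitted).
#' @return object of class `fitted_ellipsoid`: list with `center` (mm, in
#'   the voxel-index frame), `semi_axes` (mm, sorted decreasing),
#'   `orientation` (3 x 3 rotation, columns = axis directions, det +1).
#' @export
fit_ellipsoid <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  idx <- which(mask)
  if (length(idx) < 4) stop("need at least 4 voxels to fit an ellipsoid",
                            call. = FALSE)
  pts <- sweep(arrayInd(idx, dim(mask)), 2, as.numeric(spacing), "*")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  cv <- crossprod(cen) / nrow(cen)          # population covariance
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    stop("degenerate (planar) mask: covariance is rank-deficient",
         call. = FALSE)
  }
  R <- eg$vectors
  if (det(R) < 0) R[, 3] <- -R[, 3]
  structure(list(center = ctr, semi_axes = sqrt(5 * eg$values),
                 orientation = R),
            class = "fitted_ellipsoid")
}

#' @export
print.fitted_ellipsoid <- function(x, ...) {
  cat(sprintf("<fitted_ellipsoid> semi-axes (%s) mm, center (%s) mm\n",
              paste(signif(x$semi_axes, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

## Normalized radial coordinate r of voxel centers: r <= 1 is inside.
## `pts` are mm coordinates in the voxel-index frame.
ellipsoid_r <- function(pts, ell) {
  u <- sweep(pts, 2, ell$center) %*% ell$orientation
  sqrt(pmax(rowSums(sweep(u, 2, ell$semi_axes, "/")^2), 0))
}

## Logical array over the grid: voxel center inside the ellipsoid.
rasterize_ellipsoid <- function(ell, dims, spacing) {
  bb_lo <- pmax(floor((ell$center - max(ell$semi_axes)) / spacing) - 1, 1)
  bb_hi <- pmin(ceiling((ell$center + max(ell$semi_axes)) / spacing) + 1, dims)
  out <- array(FALSE, dims)
  if (any(bb_lo > bb_hi)) return(out)
  gz <- bb_lo[1]:bb_hi[1]; gy <- bb_lo[2]:bb_hi[2]; gx <- bb_lo[3]:bb_hi[3]
  pts <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
  r <- ellipsoid_r(sweep(pts, 2, as.numeric(spacing), "*"), ell)
  sub <- array(r <= 1, c(length(gz), length(gy), length(gx)))
  out[gz, gy, gx] <- sub
  out
}

#' Surface area of an ellipsoid (Thomsen approximation)
#'
#' `4*pi*((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p)` with `p = 1.6075`
#' (relative error below 1.1%).
#'
#' @param semi_axes numeric length-3 semi-axes.
#' @return area in squared units of the axes.
#' @export
ellipsoid_area <- function(semi_axes) {
  p <- 1.6075
  a <- semi_axes[1]; b <- semi_axes[2]; c <- semi_axes[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Axis, surface and volume-covering ratios
#'
#' `E_A` = longest/shortest semi-axis; `E_S` = lesion mesh surface area /
#' ellipsoid surface area (Thomsen); `E_V` = fraction of lesion voxels whose
#' centers lie inside the fitted ellipsoid.
#'
#' @param mask a [lesion_mask()].
#' @param ell a [fit_ellipsoid()] result (refit if omitted).
#' @param smooth_iter surface-mesh smoothing iterations.
#' @return named numeric vector `c(E_A, E_S, E_V)`.
#' @export
ellipsoid_ratios <- function(mask, ell = NULL, smooth_iter = 100L,
                             lesion_area = NULL) {
  if (is.null(ell)) ell <- fit_ellipsoid(mask)
  if (is.null(lesion_area)) {
    lesion_area <- surface_area(mask, smooth_iter = smooth_iter)
  }
  idx <- which(mask$data)
  pts <- sweep(arrayInd(idx, dim(mask$data)), 2, mask$spacing, "*")
  r <- ellipsoid_r(pts, ell)
  c(E_A = ell$semi_axes[1] / ell$semi_axes[3],
    E_S = lesion_area / ellipsoid_area(ell$semi_axes),
    E_V = mean(r <= 1))
}

#' Residual regions between lesion and fitted ellipsoid
#'
#' 26-connected components of the set differences lesion-minus-ellipsoid
#' ("outside" regions, protrusions) and ellipsoid-minus-lesion ("inside"
#' regions, indentations), after discarding components smaller than
#' `min_size` voxels (discretization slivers; default 27, one 3x3x3 cell).
#'
#' @param mask a [lesion_mask()].
#' @param ell a [fit_ellipsoid()] result (refit if omitted).
#' @param min_size sliver threshold in voxels.
#' @return list with counts `E_RO`, `E_RI` and integer label arrays
#'   `outside_labels`, `inside_labels` (0 = background).
#' @export
residual_regions <- function(mask, ell = NULL, min_size = 27L) {
  if (is.null(ell)) ell <- fit_ellipsoid(mask)
  E <- rasterize_ellipsoid(ell, dim(mask$data), mask$spacing)
  count_filtered <- function(m) {
    lab <- label_components(m, connectivity = 26)
    if (max(lab) == 0L) return(list(n = 0L, lab = lab))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_size)
    lab[!(lab %in% keep)] <- 0L
    # relabel 1..k
    if (length(keep)) lab[lab > 0L] <- match(lab[lab > 0L], sort(keep))
    list(n = length(keep), lab = lab)
  }
  ro <- count_filtered(mask$data & !E)
  ri <- count_filtered(E & !mask$data)
  list(E_RO = ro$n, E_RI = ri$n,
       outside_labels = ro$lab, inside_labels = ri$lab)
}

#' Angularity counts of residual regions
#'
#' A residual region "has angularity" when it protrudes sharply from the
#' ellipsoid surface: its sharpness `s` = (maximal radial distance of any
#' region voxel from the ellipsoid surface) / (equivalent radius of the
#' region's radial footprint on the surface) exceeds `threshold`. Radial
#' distance is measured along the ray to the center (a monotone surrogate
#' for the exact point-to-ellipsoid distance); the footprint radius is
#' `sqrt(2)` times the RMS spread of the region's surface projections. A
#' hemispherical bump sits near `s = 1`; spikes score higher, shallow
#' pancakes lower.
#'
#' @param regions result of [residual_regions()].
#' @param mask the [lesion_mask()] (for spacing and shape).
#' @param ell the [fit_ellipsoid()] result.
#' @param threshold sharpness threshold `s*` (default 1.0).
#' @return named integer vector `c(E_ROa, E_RIa)`.
#' @export
angularity_counts <- function(regions, mask, ell, threshold = 1.0) {
  spacing <- mask$spacing
  dims <- dim(mask$data)
  count_sharp <- function(lab) {
    k <- max(lab)
    if (k == 0L) return(0L)
    sharp <- 0L
    for (g in seq_len(k)) {
      idx <- which(lab == g)
      pts <- sweep(arrayInd(idx, dims), 2, as.numeric(spacing), "*")
      r <- ellipsoid_r(pts, ell)
      u <- sweep(pts, 2, ell$center)
      nrm <- sqrt(rowSums(u^2))
      depth <- ifelse(r > 0, nrm * abs(r - 1) / r, max(ell$semi_axes))
      proj <- u * ifelse(r > 0, 1 / r, 0)   # radial projection to surface
      ctr <- colMeans(proj)
      spread <- sqrt(mean(rowSums(sweep(proj, 2, ctr)^2)))
      rf <- max(sqrt(2) * spread, mean(spacing) / 2)
      if (max(depth) / rf > threshold) sharp <- sharp + 1L
    }
    sharp
  }
  c(E_ROa = count_sharp(regions$outside_labels),
    E_RIa = count_sharp(regions$inside_labels))
}

#' The nine ellipsoid-fitting features
#'
#' @param mask a [lesion_mask()].
#' @param min_size sliver threshold (voxels) for residual regions.
#' @param angularity_threshold sharpness threshold `s*`.
#' @param smooth_iter surface-mesh smoothing iterations.
#' @return named numeric vector
#'   `c(E_A, E_S, E_V, E_RO, E_RI, E_R, E_ROa, E_RIa, E_Ra)` with
#'   `E_R = E_RO + E_RI` and `E_Ra = E_ROa + E_RIa`.
#' @export
ellipsoid_features <- function(mask, min_size = 27L,
                               angularity_threshold = 1.0,
                               smooth_iter = 100L, lesion_area = NULL) {
  ell <- fit_ellipsoid(mask)
  ratios <- ellipsoid_ratios(mask, ell, smooth_iter = smooth_iter,
                             lesion_area = lesion_area)
  reg <- residual_regions(mask, ell, min_size = min_size)
  ang <- angularity_counts(reg, mask, ell, threshold = angularity_threshold)
  c(ratios,
    E_RO = reg$E_RO, E_RI = reg$E_RI, E_R = reg$E_RO + reg$E_RI,
    E_ROa = unname(ang["E_ROa"]), E_RIa = unname(ang["E_RIa"]),
    E_Ra = unname(ang["E_ROa"] + ang["E_RIa"]))
}
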