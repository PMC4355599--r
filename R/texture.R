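## 3-D co-occurrence texture. The gray scale is reduced from 256 to 16
## levels on the fixed global scale, then, for each displacement vector d
## (in voxels), pair frequencies are accumulated over all voxel pairs
## (v, v+d) that both lie inside the lesion. The GLCM is directed
## (unsymmetrized); six Haralick statistics summarise each matrix.

#' Quantize 8-bit gray levels
#'
#' Maps the fixed 0-255 scale onto `levels` bins: `g -> floor(g * levels / 256)`.
#' Quantization is global (not per-lesion min-max) so that texture and
#' posterior features stay comparable across cases.
#'
#' @param x a [voxel_volume()] or an integer array with values in \[0, 255\].
#' @param levels number of output gray levels (default 16).
#' @return integer array with values in `0..levels-1`.
#' @export
quantize_gray <- function(x, levels = 16L) {
  if (inherits(x, "voxel_volume")) x <- x$data
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  q <- (x * levels) %/% 256L
  storage.mode(q) <- "integer"
  q
}

#' Build a 3-D gray-level co-occurrence matrix
#'
#' Counts, over all voxels `v` such that both `v` and `v + d` lie inside the
#' mask, the pairs of quantized levels `(q(v), q(v+d))`. Directed: `(i, j)`
#' and `(j, i)` are distinct; `glcm_3d(q, m, -d)` equals the transpose of
#' `glcm_3d(q, m, d)`.
#'
#' @param quantized integer array of quantized levels (`0..levels-1`).
#' @param mask logical array of the same shape (or a [lesion_mask()]).
#' @param d integer displacement 3-vector, in voxels.
#' @param levels number of gray levels (default 16).
#' @return object of class `glcm`: list with `counts` (levels x levels
#'   integer matrix), `d`, `n_pairs`.
#' @export
glcm_3d <- function(quantized, mask, d, levels = 16L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$data
  stopifnot(identical(dim(quantized), dim(mask)), length(d) == 3)
  d <- as.integer(d)
  dims <- dim(mask)
  # index windows such that v and v+d are both in bounds
  rng <- function(n, dd) {
    lo <- max(1L, 1L - dd); hi <- min(n, n - dd)
    if (lo > hi) integer(0) else lo:hi
  }
  i1 <- rng(dims[1], d[1]); i2 <- rng(dims[2], d[2]); i3 <- rng(dims[3], d[3])
  counts <- matrix(0L, levels, levels)
  n_pairs <- 0L
  if (length(i1) && length(i2) && length(i3)) {
    m1 <- mask[i1, i2, i3, drop = FALSE]
    m2 <- mask[i1 + d[1], i2 + d[2], i3 + d[3], drop = FALSE]
    both <- m1 & m2
    if (any(both)) {
      q1 <- quantized[i1, i2, i3, drop = FALSE][both]
      q2 <- quantized[i1 + d[1], i2 + d[2], i3 + d[3], drop = FALSE][both]
      tab <- tabulate(q1 * levels + q2 + 1L, nbins = levels * levels)
      counts <- matrix(as.integer(tab), levels, levels, byrow = TRUE)
      n_pairs <- sum(tab)
    }
  }
  structure(list(counts = counts, d = d, n_pairs = as.integer(n_pairs)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> d = (%s), %d pairs\n", paste(x$d, collapse = ","),
              x$n_pairs))
  invisible(x)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' With `p = counts / n_pairs` over levels `i, j = 0..L-1`:
#' angular second moment `sum(p^2)`; contrast `sum((i-j)^2 p)`; inverse
#' difference moment `sum(p / (1 + (i-j)^2))`; entropy `-sum(p log p)`
#' (natural log, `0 log 0 := 0`); dissimilarity `sum(|i-j| p)`; correlation
#' `(sum(i j p) - mu_i mu_j) / (sigma_i sigma_j)`. A matrix with zero
#' marginal variance (constant region) has correlation defined as 1.
#'
#' @param glcm a `glcm` from [glcm_3d()], or a nonnegative matrix of counts.
#' @return named numeric vector `c(ASM, Con, I, E, D, Cor)`.
#' @export
haralick_features <- function(glcm) {
  counts <- if (inherits(glcm, "glcm")) glcm$counts else as.matrix(glcm)
  n <- sum(counts)
  if (n == 0) {
    return(c(ASM = NA_real_, Con = NA_real_, I = NA_real_,
             E = NA_real_, D = NA_real_, Cor = NA_real_))
  }
  p <- counts / n
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  asm <- sum(p^2)
  con <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  nz <- p > 0
  ent <- -sum(p[nz] * log(p[nz]))
  dis <- sum(abs(i - j) * p)
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum((0:(L - 1)) * pi_); mj <- sum((0:(L - 1)) * pj)
  si <- sqrt(sum((0:(L - 1) - mi)^2 * pi_))
  sj <- sqrt(sum((0:(L - 1) - mj)^2 * pj))
  cor <- if (si * sj <= 0) 1 else (sum(i * j * p) - mi * mj) / (si * sj)
  c(ASM = asm, Con = con, I = idm, E = ent, D = dis, Cor = cor)
}

## Canonical displacement set, report order.
texture_displacements <- function() {
  list(c(1L, 1L, 1L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
}

#' The 24 co-occurrence texture features of a lesion
#'
#' Six Haralick statistics for each of the four displacement vectors
#' (1,1,1), (1,0,0), (0,1,0), (0,0,1), computed on the 16-level quantized
#' volume restricted to the lesion. A displacement along which the mask is
#' too thin to form any pair yields `NA` for its six statistics (with a
#' warning); downstream classification rejects such cases.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [lesion_mask()].
#' @param levels gray levels after quantization (default 16).
#' @return named numeric vector of length 24, names `T_ASM(1,1,1)` ...
#'   `T_Cor(0,0,1)` in report order (displacement-major).
#' @export
texture_features <- function(volume, mask, levels = 16L) {
  # restrict to the mask bounding box: pair counting is O(box volume)
  bb <- mask_bbox(mask$data, margin = 1L)
  q <- quantize_gray(crop_bbox(volume$data, bb), levels)
  m <- crop_bbox(mask$data, bb)
  out <- numeric(0)
  for (d in texture_displacements()) {
    g <- glcm_3d(q, m, d, levels)
    if (g$n_pairs == 0L) {
      warning(sprintf("degenerate GLCM for displacement (%s): no voxel pairs",
                      paste(d, collapse = ",")), call. = FALSE)
    }
    h <- haralick_features(g)
    tag <- sprintf("(%s)", paste(d, collapse = ","))
    names(h) <- paste0("T_", names(h), tag)
    out <- c(out, h)
  }
  out
}
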