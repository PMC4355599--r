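## Shared voxel-lattice helpers. All arrays are rank-3; dimension 1 is the
## beam/depth axis (larger index = deeper, i.e. further from the transducer),
## dimensions 2-3 are lateral. Every module relies on this convention.

#' Label connected components of a rank-3 logical array
#'
#' Components are defined on the voxel lattice under 26- (vertex) or
#' 6- (face) connectivity. Implemented as connected components of the voxel
#' adjacency graph.
#'
#' @param mask logical rank-3 array.
#' @param connectivity 26 (default) or 6.
#' @return integer array of the same shape; 0 is background, components are
#'   labelled 1..k in decreasing order of size.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 26))
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  offs <- if (connectivity == 6) {
    rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    # keep one representative per +/- pair (undirected edges)
    g[g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 3] > 0))), ,
      drop = FALSE]
  }
  ai <- arrayInd(idx, d)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  e_from <- integer(0); e_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni1 <- ai[, 1] + offs[r, 1]
    ni2 <- ai[, 2] + offs[r, 2]
    ni3 <- ai[, 3] + offs[r, 3]
    ok <- ni1 >= 1L & ni1 <= d[1] & ni2 >= 1L & ni2 <= d[2] &
      ni3 >= 1L & ni3 <= d[3]
    if (!any(ok)) next
    lin <- ni1[ok] + (ni2[ok] - 1L) * d[1] + (ni3[ok] - 1L) * d[1] * d[2]
    nb <- pos[lin]
    keep <- nb > 0L
    if (any(keep)) {
      e_from <- c(e_from, which(ok)[keep])
      e_to <- c(e_to, nb[keep])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(e_from)) {
    g <- igraph::add_edges(g, rbind(e_from, e_to))
  }
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  relabel <- integer(length(sizes))
  relabel[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  lab[idx] <- relabel[memb]
  lab
}

## Pad a rank-3 array by `n` layers of `value` on every side.
pad3 <- function(a, value = FALSE, n = 1L) {
  d <- dim(a)
  out <- array(value, d + 2L * n)
  out[(n + 1L):(n + d[1]), (n + 1L):(n + d[2]), (n + 1L):(n + d[3])] <- a
  out
}

## Bounding box (inclusive index ranges) of TRUE voxels, expanded by `margin`
## and clipped to the array.
mask_bbox <- function(mask, margin = 0L) {
  d <- dim(mask)
  ai <- arrayInd(which(mask), d)
  lo <- pmax(apply(ai, 2, min) - margin, 1L)
  hi <- pmin(apply(ai, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

## Separable Gaussian smoothing of a rank-3 numeric array (voxel units),
## zero-padded boundary. Used by the phantom speckle generator.
smooth_gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  conv_axis <- function(x, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(x, perm)
    dm <- dim(m)
    flat <- matrix(m, nrow = dm[1])
    n <- dm[1]
    padded <- rbind(matrix(0, r, ncol(flat)), flat, matrix(0, r, ncol(flat)))
    out <- matrix(0, n, ncol(flat))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
    }
    res <- array(out, dm)
    aperm(res, order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

## 1-D distance transform for sections that are a single pixel row/column:
## distance along the line to the nearest FALSE pixel or line end. The 2-D
## transform is useless there (every pixel has transverse background at
## distance 1).
distmap_line <- function(section) {
  d <- dim(section)
  v <- as.vector(section)
  if (d[1] > 1 && d[2] > 1) {
    # degenerate within a wider matrix: flatten along the occupied line
    ij <- which(section, arr.ind = TRUE)
    ax <- if (diff(range(ij[, 1])) == 0) 2 else 1
    out <- matrix(0, d[1], d[2])
    line <- rep(FALSE, d[ax])
    line[ij[, ax]] <- TRUE
    dl <- dist1d(line)
    out[ij] <- dl[ij[, ax]]
    return(out)
  }
  matrix(dist1d(v), d[1], d[2])
}

dist1d <- function(line) {
  n <- length(line)
  dist <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {                 # forward pass
    run <- if (line[i]) run + 1 else 0
    dist[i] <- run
  }
  run <- 0
  for (i in rev(seq_len(n))) {            # backward pass
    run <- if (line[i]) run + 1 else 0
    dist[i] <- min(dist[i], run)
  }
  dist
}

## 2-D Euclidean distance transform (distance of each TRUE pixel to the
## nearest FALSE pixel, in pixel units). The image border counts as
## background, hence the one-pixel pad before calling EBImage.
distmap2 <- function(section) {
  stopifnot(length(dim(section)) == 2)
  d <- dim(section)
  padded <- matrix(0, d[1] + 2L, d[2] + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- as.numeric(section)
  dm <- EBImage::distmap(padded, metric = "euclidean")
  as.matrix(dm)[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE]
}
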