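## Isosurface extraction for binary masks: marching tetrahedra at the 0.5
## level. Each lattice cell (8 voxel corners) is split into six tetrahedra
## sharing the main diagonal; mixed tetrahedra contribute one or two
## triangles with vertices at edge midpoints. Raw binary isosurfaces carry a
## staircase bias (a digital ball's mesh area is ~9% above 4*pi*r^2), so the
## mesh is relaxed with Taubin's shrink-compensated lambda/mu smoothing
## before the area is measured.

# 6-tetrahedron decomposition of the unit cell. Corner ids 1..8 encode
# (dz, dy, dx) offsets via bits: id = 1 + dz + 2*dy + 4*dx.
.tets <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

.corner_offsets <- cbind(
  dz = c(0, 1, 0, 1, 0, 1, 0, 1),
  dy = c(0, 0, 1, 1, 0, 0, 1, 1),
  dx = c(0, 0, 0, 0, 1, 1, 1, 1))

# Per tetra-case (index = 1 + b1 + 2*b2 + 4*b3 + 8*b4, where b_k is the
# inside-bit of the tet's k-th corner): list of triangles, each a 3-list of
# crossing edges given as pairs of local tet corners (1..4).
.tet_cases <- local({
  cases <- vector("list", 16)
  edge <- function(a, b) c(a, b)
  tri <- function(e1, e2, e3) list(e1, e2, e3)
  one_in <- function(v) {
    o <- setdiff(1:4, v)
    list(tri(edge(v, o[1]), edge(v, o[2]), edge(v, o[3])))
  }
  two_in <- function(v) {
    o <- setdiff(1:4, v)
    # quad over edges (v1,o1)-(v1,o2)-(v2,o2)-(v2,o1), split into 2 triangles
    e1 <- edge(v[1], o[1]); e2 <- edge(v[1], o[2])
    e3 <- edge(v[2], o[2]); e4 <- edge(v[2], o[1])
    list(tri(e1, e2, e3), tri(e1, e3, e4))
  }
  for (code in 0:15) {
    bits <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)))
    inside <- which(bits)
    cases[[code + 1]] <- switch(as.character(length(inside)),
      "0" = list(), "4" = list(),
      "1" = one_in(inside),
      "3" = one_in(setdiff(1:4, inside)),
      "2" = two_in(inside))
  }
  cases
})

#' Extract the 0.5-level surface mesh of a binary mask
#'
#' Marching tetrahedra on the (one-voxel zero-padded) mask, vertices at edge
#' midpoints scaled by the voxel spacing, followed by `smooth_iter` rounds of
#' Taubin lambda/mu mesh smoothing (volume-preserving staircase removal).
#'
#' @param mask logical rank-3 array or [lesion_mask()].
#' @param spacing voxel spacing in mm (taken from the mask if omitted).
#' @param smooth_iter Taubin smoothing iterations (default 100; 0 = raw mesh).
#' @param lambda,mu Taubin coefficients.
#' @return list with `vertices` (n x 3, mm) and `faces` (m x 3 vertex ids).
#' @export
surface_mesh <- function(mask, spacing = NULL, smooth_iter = 100L,
                         lambda = 0.5, mu = -0.505) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  m <- pad3(mask, FALSE, 1L)
  d <- dim(m)
  v <- array(0L, d); v[m] <- 1L
  dc <- d - 1L  # cell grid
  corner_val <- function(k) {
    off <- .corner_offsets[k, ]
    v[(1L + off[1]):(dc[1] + off[1]),
      (1L + off[2]):(dc[2] + off[2]),
      (1L + off[3]):(dc[3] + off[3]), drop = FALSE]
  }
  s <- corner_val(1)
  for (k in 2:8) s <- s + corner_val(k)
  mixed <- which(s > 0L & s < 8L)
  if (!length(mixed)) stop("mask has no surface (empty or full grid)",
                           call. = FALSE)
  ci <- arrayInd(mixed, dc)          # cell base coordinates (1-based)
  nmix <- nrow(ci)
  # global linear id and inside-bit of each of the 8 corners for mixed cells
  corner_id <- matrix(0, nmix, 8)
  corner_bit <- matrix(FALSE, nmix, 8)
  for (k in 1:8) {
    off <- .corner_offsets[k, ]
    z <- ci[, 1] + off[1]; y <- ci[, 2] + off[2]; x <- ci[, 3] + off[3]
    lin <- z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
    corner_id[, k] <- lin
    corner_bit[, k] <- v[lin] == 1L
  }
  # accumulate triangles as edge-pairs of global corner ids
  ea <- list(); eb <- list(); nt <- 0L
  for (t in seq_len(nrow(.tets))) {
    tc <- .tets[t, ]
    code <- corner_bit[, tc[1]] + 2L * corner_bit[, tc[2]] +
      4L * corner_bit[, tc[3]] + 8L * corner_bit[, tc[4]]
    for (cs in unique(code)) {
      tris <- .tet_cases[[cs + 1L]]
      if (!length(tris)) next
      rows <- which(code == cs)
      for (tr in tris) {
        nt <- nt + 1L
        a <- matrix(0, length(rows), 3); b <- a
        for (e in 1:3) {
          a[, e] <- corner_id[rows, tc[tr[[e]][1]]]
          b[, e] <- corner_id[rows, tc[tr[[e]][2]]]
        }
        ea[[nt]] <- a; eb[[nt]] <- b
      }
    }
  }
  A <- do.call(rbind, ea); B <- do.call(rbind, eb)
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- (lo - 1) * prod(d) + (hi - 1)      # < 2^53 for grids up to ~400^3
  ukey <- sort(unique(as.vector(key)))
  faces <- matrix(match(key, ukey), ncol = 3)
  klo <- ukey %/% prod(d) + 1; khi <- ukey %% prod(d) + 1
  coord <- function(lin) {
    lin0 <- lin - 1
    z <- lin0 %% d[1]
    y <- (lin0 %/% d[1]) %% d[2]
    x <- lin0 %/% (d[1] * d[2])
    cbind(z, y, x)
  }
  verts <- (coord(klo) + coord(khi)) / 2
  verts <- sweep(verts, 2, as.numeric(spacing), "*")
  if (smooth_iter > 0) {
    verts <- taubin_smooth(verts, faces, smooth_iter, lambda, mu)
  }
  list(vertices = verts, faces = faces)
}

## Taubin smoothing: alternate Laplacian steps with positive (lambda) and
## negative (mu) weights; |mu| slightly > lambda compensates shrinkage.
taubin_smooth <- function(verts, faces, iter, lambda, mu) {
  n <- nrow(verts)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
  e <- e[!duplicated(key), , drop = FALSE]
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  W <- methods::as(Matrix::Diagonal(x = 1 / deg) %*% adj, "CsparseMatrix")
  V <- Matrix::Matrix(verts)
  for (k in seq_len(iter)) {
    V <- V + lambda * (W %*% V - V)
    V <- V + mu * (W %*% V - V)
  }
  as.matrix(V)
}

#' Total area of a triangle mesh
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3).
#' @return total area (mm^2 if vertices are in mm).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}
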