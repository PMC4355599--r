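# Geometric fixtures built in code. All masks are plain logical arrays;
# wrap with lesion_mask() where a spacing-aware object is needed.

# digital ball of radius r voxels, centered in a grid with `pad` margin
digital_ball <- function(r, pad = 2L) {
  n <- 2L * r + 1L + 2L * pad
  c0 <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, c(n, n, n))
}

# axis-aligned solid box of the given side lengths, with margin
digital_box <- function(sides, pad = 2L) {
  d <- sides + 2L * pad
  m <- array(FALSE, d)
  m[(pad + 1L):(pad + sides[1]), (pad + 1L):(pad + sides[2]),
    (pad + 1L):(pad + sides[3])] <- TRUE
  m
}

# rasterized axis-aligned ellipsoid with semi-axes in voxels
digital_ellipsoid <- function(semi_axes, pad = 3L, dims = NULL) {
  if (is.null(dims)) dims <- ceiling(2 * semi_axes) + 2L * pad + 1L
  ctr <- (dims + 1) / 2
  g <- expand.grid(z = 1:dims[1], y = 1:dims[2], x = 1:dims[3])
  r2 <- ((g$z - ctr[1]) / semi_axes[1])^2 + ((g$y - ctr[2]) / semi_axes[2])^2 +
    ((g$x - ctr[3]) / semi_axes[3])^2
  array(r2 <= 1, dims)
}

# add a solid ball bump of radius rb centered at `at` (voxel coords)
add_ball <- function(mask, at, rb) {
  d <- dim(mask)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  d2 <- (g$z - at[1])^2 + (g$y - at[2])^2 + (g$x - at[3])^2
  mask | array(d2 <= rb^2, d)
}

# constant-gray volume wrapped as voxel_volume
const_volume <- function(dims, value, spacing = c(1, 1, 1)) {
  voxel_volume(array(value, dims), spacing)
}

# small feature table with the full 44-column schema filled from a matrix
fake_feature_table <- function(x) {
  stopifnot(ncol(x) == 44)
  colnames(x) <- feature_names()
  as.data.frame(x, check.names = FALSE)
}
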