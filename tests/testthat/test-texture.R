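# Brute-force pair-enumeration oracle for co-occurrence counting, kept
# independent of the vectorized implementation.
glcm_oracle <- function(q, mask, d, levels = 16L) {
  dm <- dim(mask)
  counts <- matrix(0L, levels, levels)
  for (z in 1:dm[1]) for (y in 1:dm[2]) for (x in 1:dm[3]) {
    z2 <- z + d[1]; y2 <- y + d[2]; x2 <- x + d[3]
    if (z2 < 1 || z2 > dm[1] || y2 < 1 || y2 > dm[2] || x2 < 1 || x2 > dm[3])
      next
    if (mask[z, y, x] && mask[z2, y2, x2]) {
      i <- q[z, y, x] + 1L; j <- q[z2, y2, x2] + 1L
      counts[i, j] <- counts[i, j] + 1L
    }
  }
  counts
}

test_that("quantization maps the fixed 0-255 scale to floor(g/16)", {
  expect_equal(quantize_gray(array(0L, c(1, 1, 1)))[1], 0L)
  expect_equal(quantize_gray(array(255L, c(1, 1, 1)))[1], 15L)
  expect_equal(quantize_gray(array(16L, c(1, 1, 1)))[1], 1L)
  expect_equal(quantize_gray(array(15L, c(1, 1, 1)))[1], 0L)
  g <- array(sample(0:255, 4^3, TRUE), c(4, 4, 4))
  expect_equal(quantize_gray(g), array(g %/% 16L, dim(g)))
  expect_error(quantize_gray(g, levels = 1), "levels")
})

test_that("co-occurrence counting matches brute-force pair enumeration", {
  # constant 8^3 cube: one diagonal cell, 7*8*8 pairs along axis 1
  m <- digital_box(c(8L, 8L, 8L), pad = 1L)
  q <- quantize_gray(array(100L, dim(m)))
  g <- glcm_3d(q, m, c(1, 0, 0))
  expect_equal(g$n_pairs, 448L)
  expect_equal(g$counts[7, 7], 448L)   # level 6 (100 %/% 16), 1-based cell
  expect_equal(sum(g$counts), g$n_pairs)
  # random volume and mask agree with the oracle for all four displacements
  set.seed(42)
  q <- array(sample(0:15, 6^3, TRUE), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.6, c(6, 6, 6))
  for (d in list(c(1, 1, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 2, 0))) {
    g <- glcm_3d(q, mask, d)
    expect_identical(g$counts, glcm_oracle(q, mask, d))
  }
})

test_that("two-voxel masks give a single directed pair or a degenerate GLCM", {
  q <- array(0L, c(3, 1, 1)); q[1, 1, 1] <- 3L * 16L; q[2, 1, 1] <- 5L * 16L
  m <- array(FALSE, c(3, 1, 1)); m[1:2, 1, 1] <- TRUE
  g <- glcm_3d(quantize_gray(q), m, c(1, 0, 0))
  expect_equal(g$n_pairs, 1L)
  expect_equal(g$counts[4, 6], 1L)
  g0 <- glcm_3d(quantize_gray(q), m, c(0, 0, 1))
  expect_equal(g0$n_pairs, 0L)
  expect_true(all(is.na(haralick_features(g0))))
})

test_that("negating the displacement transposes the directed GLCM", {
  set.seed(7)
  q <- array(sample(0:15, 8^3, TRUE), c(8, 8, 8))
  mask <- array(runif(8^3) < 0.7, c(8, 8, 8))
  for (d in list(c(1, 1, 1), c(1, 0, 0), c(0, 1, 1))) {
    expect_identical(glcm_3d(q, mask, -d)$counts, t(glcm_3d(q, mask, d)$counts))
  }
})

test_that("Haralick statistics match hand-evaluated cases", {
  # all mass at one diagonal cell
  c1 <- matrix(0L, 16, 16); c1[4, 4] <- 10L
  h <- haralick_features(c1)
  expect_equal(unname(h), c(1, 0, 1, 0, 0, 1))
  # half at (0,1), half at (1,0): Con = 1, D = 1, ASM = 0.5, E = ln 2
  c2 <- matrix(0L, 16, 16); c2[1, 2] <- 5L; c2[2, 1] <- 5L
  h2 <- haralick_features(c2)
  expect_equal(unname(h2["Con"]), 1)
  expect_equal(unname(h2["D"]), 1)
  expect_equal(unname(h2["ASM"]), 0.5)
  expect_equal(unname(h2["E"]), log(2))
  expect_equal(unname(h2["Cor"]), -1)  # perfectly anti-correlated two-cell case
})

test_that("Haralick statistics respect their analytic bounds", {
  set.seed(3)
  for (rep in 1:20) {
    counts <- matrix(rpois(256, 2), 16, 16)
    if (sum(counts) == 0) counts[1, 1] <- 1L
    h <- haralick_features(counts)
    expect_gte(h[["E"]], 0)
    expect_gt(h[["ASM"]], 0); expect_lte(h[["ASM"]], 1)
    expect_gte(h[["Cor"]], -1 - 1e-12); expect_lte(h[["Cor"]], 1 + 1e-12)
    expect_gte(h[["I"]], 0); expect_lte(h[["I"]], 1)
  }
})

test_that("the 24 texture features come in report order and handle constants", {
  vol <- const_volume(c(20, 20, 20), 100)
  m <- digital_box(c(8L, 8L, 8L), pad = 6L)
  msk <- lesion_mask(m, c(1, 1, 1))
  tf <- texture_features(vol, msk)
  expect_length(tf, 24)
  expect_identical(names(tf), feature_names()[1:24])
  for (d in c("(1,1,1)", "(1,0,0)", "(0,1,0)", "(0,0,1)")) {
    expect_equal(unname(tf[paste0("T_ASM", d)]), 1)
    expect_equal(unname(tf[paste0("T_Con", d)]), 0)
    expect_equal(unname(tf[paste0("T_I", d)]), 1)
    expect_equal(unname(tf[paste0("T_E", d)]), 0)
    expect_equal(unname(tf[paste0("T_D", d)]), 0)
    expect_equal(unname(tf[paste0("T_Cor", d)]), 1)  # degenerate convention
  }
})

test_that("uncorrelated noise has near-zero co-occurrence correlation", {
  set.seed(99)
  m <- digital_ball(14, 1)
  d <- dim(m)
  vol <- voxel_volume(array(sample(0:255, prod(d), TRUE), d))
  msk <- lesion_mask(m, c(1, 1, 1))
  tf <- texture_features(vol, msk)
  for (nm in grep("T_Cor", names(tf), value = TRUE)) {
    expect_lt(abs(tf[[nm]]), 0.05)
  }
})

test_that("texture features are invariant to lesion translation and bin-safe shifts", {
  set.seed(12)
  d <- c(24, 24, 24)
  g <- array(sample(0:223, prod(d), TRUE), d)
  m <- array(FALSE, d); m[4:11, 4:11, 4:11] <- TRUE
  f1 <- texture_features(voxel_volume(g), lesion_mask(m, c(1, 1, 1)))
  # translate lesion and its gray content by (6, 7, 5)
  g2 <- array(0L, d); m2 <- array(FALSE, d)
  g2[10:17, 11:18, 9:16] <- g[4:11, 4:11, 4:11]
  m2[10:17, 11:18, 9:16] <- TRUE
  f2 <- texture_features(voxel_volume(g2), lesion_mask(m2, c(1, 1, 1)))
  expect_equal(f1, f2)
  # +16 gray shift moves every voxel one whole bin: Con and D unchanged
  f3 <- texture_features(voxel_volume(g + 16L), lesion_mask(m, c(1, 1, 1)))
  for (nm in grep("T_Con|T_D", names(f1), value = TRUE)) {
    expect_equal(f1[[nm]], f3[[nm]])
  }
})
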