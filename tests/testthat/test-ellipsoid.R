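test_that("moment fitting recovers a rasterized ellipsoid's axes", {
  m <- lesion_mask(digital_ellipsoid(c(20, 12, 8)), c(1, 1, 1))
  ell <- fit_ellipsoid(m)
  expect_lt(max(abs(ell$semi_axes - c(20, 12, 8)) / c(20, 12, 8)), 0.05)
  expect_equal(det(ell$orientation), 1, tolerance = 1e-9)
  expect_equal(crossprod(ell$orientation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # a ball has three nearly equal semi-axes
  eb <- fit_ellipsoid(lesion_mask(digital_ball(15), c(1, 1, 1)))
  expect_lt(diff(range(eb$semi_axes)) / mean(eb$semi_axes), 0.05)
})

test_that("rotating the mask by 90 degrees permutes the axes, lengths unchanged", {
  m <- digital_ellipsoid(c(16, 10, 7))
  ell1 <- fit_ellipsoid(lesion_mask(m, c(1, 1, 1)))
  rot <- aperm(m, c(1, 3, 2))  # 90-degree rotation about the depth axis
  ell2 <- fit_ellipsoid(lesion_mask(rot, c(1, 1, 1)))
  expect_equal(ell1$semi_axes, ell2$semi_axes, tolerance = 0.01)
})

test_that("planar masks are rejected as degenerate", {
  flat <- array(FALSE, c(8, 8, 8)); flat[4, 2:7, 2:7] <- TRUE
  expect_error(fit_ellipsoid(lesion_mask(flat, c(1, 1, 1))), "degenerate")
})

test_that("a self-fit ellipsoid has matching ratios and no residual regions", {
  for (ax in list(c(14, 10, 8), c(18, 12, 7))) {
    m <- lesion_mask(digital_ellipsoid(ax), c(1, 1, 1))
    ell <- fit_ellipsoid(m)
    rat <- ellipsoid_ratios(m, ell)
    expect_equal(unname(rat["E_A"]), ax[1] / ax[3], tolerance = 0.05)
    expect_gt(rat[["E_S"]], 0.9); expect_lt(rat[["E_S"]], 1.1)
    expect_gte(rat[["E_V"]], 0.95)
    reg <- residual_regions(m, ell)
    expect_equal(reg$E_RO, 0)
    expect_equal(reg$E_RI, 0)
  }
})

test_that("volume covering of the self-fit approaches 1 with resolution", {
  ev <- vapply(c(10, 20, 40), function(r) {
    m <- lesion_mask(digital_ball(r), c(1, 1, 1))
    ellipsoid_ratios(m, fit_ellipsoid(m))[["E_V"]]
  }, numeric(1))
  expect_true(all(diff(ev) >= 0))
  expect_gte(ev[1], 0.95)
  expect_gte(ev[3], 0.99)
})

test_that("attached bumps are counted as outside residual regions", {
  ax <- c(16, 12, 10)
  base <- digital_ellipsoid(ax, pad = 8L)
  d <- dim(base); ctr <- (d + 1) / 2
  # one small bump on a pole (under 5% of the lesion volume)
  bump1 <- add_ball(base, c(ctr[1], ctr[2] + ax[2] + 1, ctr[3]), 4)
  m1 <- lesion_mask(bump1, c(1, 1, 1))
  reg1 <- residual_regions(m1, fit_ellipsoid(m1))
  expect_equal(reg1$E_RO, 1)
  # two bumps on opposite poles
  bump2 <- add_ball(bump1, c(ctr[1], ctr[2] - ax[2] - 1, ctr[3]), 4)
  m2 <- lesion_mask(bump2, c(1, 1, 1))
  reg2 <- residual_regions(m2, fit_ellipsoid(m2))
  expect_equal(reg2$E_RO, 2)
  # the bump strictly lowers the covering ratio vs the bump-free fixture
  m0 <- lesion_mask(base, c(1, 1, 1))
  ev0 <- ellipsoid_ratios(m0, fit_ellipsoid(m0))[["E_V"]]
  ev1 <- ellipsoid_ratios(m1, fit_ellipsoid(m1))[["E_V"]]
  expect_lt(ev1, ev0)
})

test_that("angularity separates spikes from shallow pancake bumps", {
  ax <- c(16, 12, 10)
  base <- digital_ellipsoid(ax, pad = 12L)
  d <- dim(base); ctr <- (d + 1) / 2
  # spike: thin rod of length 10, footprint radius ~2
  spike <- base
  spike[ctr[1] + (-2:2), round(ctr[2] + ax[2] + (-2)):round(ctr[2] + ax[2] + 10),
        ctr[3] + (-2:2)] <- TRUE
  ms <- lesion_mask(spike, c(1, 1, 1))
  ells <- fit_ellipsoid(ms)
  regs <- residual_regions(ms, ells)
  expect_equal(regs$E_RO, 1)
  angs <- angularity_counts(regs, ms, ells)
  expect_equal(unname(angs["E_ROa"]), 1L)
  # pancake: wide shallow cap (footprint ~ whole flank, depth ~2)
  pan <- base
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  r2 <- ((g$z - ctr[1]) / (ax[1] + 2))^2 + ((g$y - ctr[2]) / (ax[2] + 2))^2 +
    ((g$x - ctr[3]) / (ax[3] + 2))^2
  shell <- array(r2 <= 1, d) & !base & (g$y > ctr[2] + 2)
  pan <- pan | array(shell, d)
  mp <- lesion_mask(pan, c(1, 1, 1))
  ellp <- fit_ellipsoid(mp)
  regp <- residual_regions(mp, ellp)
  if (regp$E_RO > 0) {
    angp <- angularity_counts(regp, mp, ellp)
    expect_equal(unname(angp["E_ROa"]), 0L)
  }
  # no residual regions -> no angularity
  mb <- lesion_mask(digital_ball(12), c(1, 1, 1))
  ellb <- fit_ellipsoid(mb)
  regb <- residual_regions(mb, ellb)
  expect_equal(unname(angularity_counts(regb, mb, ellb)), c(0L, 0L))
})

test_that("the nine features satisfy their identities on varied fixtures", {
  fixtures <- list(
    lesion_mask(digital_ball(12), c(1, 1, 1)),
    lesion_mask(digital_ellipsoid(c(15, 11, 8)), c(1, 1, 1)),
    lesion_mask(add_ball(digital_ellipsoid(c(14, 11, 9), pad = 8L),
                         c(12, 20, 20), 5), c(1, 1, 1)))
  for (m in fixtures) {
    ef <- ellipsoid_features(m)
    expect_identical(names(ef), feature_names()[31:39])
    expect_equal(ef[["E_R"]], ef[["E_RO"]] + ef[["E_RI"]])
    expect_equal(ef[["E_Ra"]], ef[["E_ROa"]] + ef[["E_RIa"]])
    expect_lte(ef[["E_ROa"]], ef[["E_RO"]])
    expect_lte(ef[["E_RIa"]], ef[["E_RI"]])
    expect_gte(ef[["E_A"]], 1)
    expect_gte(ef[["E_V"]], 0); expect_lte(ef[["E_V"]], 1)
  }
  ball <- ellipsoid_features(lesion_mask(digital_ball(12), c(1, 1, 1)))
  expect_lt(abs(ball[["E_A"]] - 1), 0.05)
  expect_equal(ball[["E_R"]], 0)
  expect_equal(ball[["E_Ra"]], 0)
})

test_that("rigid 90-degree rotations leave the nine features unchanged", {
  m <- add_ball(digital_ellipsoid(c(14, 10, 8), pad = 8L), c(10, 18, 18), 5)
  f1 <- ellipsoid_features(lesion_mask(m, c(1, 1, 1)))
  f2 <- ellipsoid_features(lesion_mask(aperm(m, c(1, 3, 2)), c(1, 1, 1)))
  for (nm in c("E_RO", "E_RI", "E_R", "E_ROa", "E_RIa", "E_Ra")) {
    expect_equal(f1[[nm]], f2[[nm]])
  }
  for (nm in c("E_A", "E_S", "E_V")) {
    expect_lt(abs(f1[[nm]] - f2[[nm]]) / max(f1[[nm]], 1e-9), 0.02)
  }
})
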