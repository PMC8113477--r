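test_that("q3 of a single +z neighbor has only the m=0 component", {
  q <- q3_vector(c(0, 0, 0), rbind(c(0, 0, 2.8)))
  expect_equal(Mod(q[c(1:3, 5:7)]), rep(0, 6), tolerance = 1e-12)
  expect_gt(Mod(q[4]), 0.7)   # sqrt(7/(16 pi)) * 2 = 0.746
})

test_that("q3 magnitude matches the spherical-harmonics oracle on a tetrahedron", {
  ## reference values computed independently with scipy.special.sph_harm_y
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  q <- q3_vector(c(0, 0, 0), tet * 2.75)
  expect_equal(sqrt(sum(Mod(q)^2)), 0.5562984315, tolerance = 1e-9)
  expect_equal(q[2], complex(real = 0, imaginary = -0.3933623933), tolerance = 1e-9)
  expect_equal(Mod(q[c(1, 3, 4, 5, 7)]), rep(0, 5), tolerance = 1e-9)
})

test_that("|q3| is rotation invariant and c_ij transforms covariantly", {
  set.seed(31)
  nb <- matrix(rnorm(12), 4, 3) * 2
  q0 <- q3_vector(c(0, 0, 0), nb)
  for (i in 1:3) {
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    qr_ <- q3_vector(c(0, 0, 0), nb %*% rot)
    expect_equal(sqrt(sum(Mod(qr_)^2)), sqrt(sum(Mod(q0)^2)), tolerance = 1e-10)
  }
})

test_that("bond correlation is 1 for identical vectors and errors on zero norm", {
  q <- q3_vector(c(0, 0, 0), matrix(rnorm(12), 4, 3))
  expect_equal(bond_correlation(q, q), 1.0, tolerance = 1e-12)
  expect_error(bond_correlation(q, rep(0 + 0i, 7)), "zero")
  expect_error(q3_vector(c(0, 0, 0), rbind(c(0, 0, 0))), "zero-length")
})

test_that("ideal lattice bonds evaluate staggered and eclipsed as expected", {
  ice <- ice_333()
  wp <- classify_waters(ice$oxygen, ice$box)
  cv <- wp$bonds$c
  staggered <- cv[cv <= -0.8]
  eclipsed <- cv[cv > -0.8]
  expect_equal(length(staggered) / length(cv), 0.75, tolerance = 0.01)
  expect_true(all(abs(staggered - (-1)) < 1e-6))
  expect_true(all(eclipsed >= -0.35 & eclipsed <= 0.25))
})

test_that("interior of a proton-disordered Ih slab is >=95% hexagonal ice", {
  ice <- ice_333()
  wp <- classify_waters(ice$oxygen, ice$box)
  expect_gte(mean(wp$label == "HEX"), 0.95)
})

test_that("a random liquid box is >=95% non-ice", {
  lb <- liquid_25()
  o <- frame_coords(lb, 1)[water_o_idx(lb), ]
  wp <- classify_waters(o, lb$box)
  expect_gte(mean(!ice_like(wp$label)), 0.95)
  ## and the strict liquid label still dominates
  expect_gt(mean(wp$label == "LIQ"), 0.5)
})

test_that("degenerate inputs fall back to liquid", {
  expect_message(wp <- classify_waters(matrix(rnorm(9), 3, 3), c(50, 50, 50)),
                 "fewer than 4")
  expect_true(all(wp$label == "LIQ"))
  expect_length(wp$label, 3)
})

test_that("label counts are conserved and classification is rigid-motion invariant", {
  ice <- build_ice_ih(c(2, 2, 2), seed = 3)
  wp <- classify_waters(ice$oxygen, ice$box)
  expect_equal(sum(table(wp$label)), nrow(ice$oxygen))

  ## open-boundary cluster: global rotation + translation leaves labels alone
  set.seed(11)
  sub <- ice$oxygen
  wp0 <- classify_waters(sub, box = NULL)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- sweep(sub %*% rot, 2, c(13.7, -8.1, 4.2), "+")
  wp1 <- classify_waters(moved, box = NULL)
  expect_identical(wp0$label, wp1$label)

  ## periodic image shift with wrapping leaves per-molecule labels unchanged
  shifted <- icebindr:::wrap_box(sweep(ice$oxygen, 2, ice$box * 0.37, "+"), ice$box)
  wp2 <- classify_waters(shifted, ice$box)
  expect_identical(wp$label, wp2$label)
})

test_that("melting jitter never increases the hexagonal fraction on average", {
  hex_frac <- function(sigma, seed) {
    ice <- build_ice_ih(c(2, 2, 2), seed = seed)
    o <- ice$oxygen + matrix(withr::with_seed(seed + 100, rnorm(length(ice$oxygen))),
                             ncol = 3) * sigma
    mean(classify_waters(o, ice$box)$label == "HEX")
  }
  sigmas <- c(0, 0.25, 0.5)
  means <- sapply(sigmas, function(s) mean(sapply(1:3, function(seed) hex_frac(s, seed))))
  expect_true(all(diff(means) <= 1e-9))
  expect_gt(means[1], 0.95)
  expect_lt(means[3], 0.5)
})

test_that("clathrate fraction counts clathrate-like labels in the shell", {
  ## constructed labels on a synthetic line of waters around a probe
  coords <- cbind(seq(0, 9) * 1.0, 0, 0)
  lab <- structure(list(label = factor(c(rep("CLATH", 3), rep("INT_CLATH", 2),
                                         rep("LIQ", 5)),
                                       levels = icebindr:::PHASE_LEVELS)),
                   class = "water_phase_labels")
  probe <- rbind(c(4.5, 0, 0))
  expect_equal(clathrate_fraction(lab, coords, probe, r = 100), 0.5)
  lab_liq <- structure(list(label = factor(rep("LIQ", 10),
                                           levels = icebindr:::PHASE_LEVELS)),
                       class = "water_phase_labels")
  expect_equal(clathrate_fraction(lab_liq, coords, probe, r = 100), 0)
  expect_true(is.na(clathrate_fraction(lab, coords, rbind(c(500, 500, 500)), r = 2)))
  expect_error(clathrate_fraction(lab, coords, probe, r = -1), "r")
})

test_that("a probe buried in bulk ice sees no clathrate-like layer", {
  ice <- ice_333()
  wp <- classify_waters(ice$oxygen, ice$box)
  center <- matrix(ice$box / 2, 1)
  expect_lt(clathrate_fraction(wp, ice$oxygen, center, r = 6, box = ice$box), 0.05)
})
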