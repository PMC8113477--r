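test_that("liquid box count and separation follow the insertion parameters", {
  lb <- build_liquid_box(c(20, 20, 20), density = 0.0334, seed = 2)
  expect_equal(sum(lb$atoms$role == "water_O"), 267)   # round(0.0334 * 8000)
  expect_equal(nrow(lb$atoms), 3 * 267)

  o <- frame_coords(lb, 1)[water_o_idx(lb), ]
  d <- icebindr:::pair_dist(o, box = lb$box)
  diag(d) <- Inf
  expect_gte(min(d), 2.4)   # exhaustive pair check

  empty <- build_liquid_box(c(10, 10, 10), density = 0, seed = 1)
  expect_equal(nrow(empty$atoms), 0)

  expect_error(build_liquid_box(c(8, 8, 8), density = 0.08, min_separation = 3,
                                seed = 1, max_tries_per_mol = 20L),
               "density")
})

test_that("scripted front stands still at v=0 and advances v*t otherwise", {
  p0 <- scripted_params(growth_rate = 0, n_frames = 20, t_bind = NA, seed = 3,
                        front_phase_jitter = FALSE)
  fs0 <- generate_trajectory(p0)
  expect_true(all(fs0$truth$front_z == fs0$truth$front_z[1]))

  p <- scripted_params(growth_rate = 0.5, n_frames = 41, t_bind = NA, seed = 3)
  fs <- generate_trajectory(p)
  expect_equal(fs$truth$front_z[41] - fs$truth$front_z[1], 0.5 * 40)
})

test_that("with zero jitter every ice-zone molecule sits exactly on a lattice site", {
  p <- scripted_params(growth_rate = 0.5, sigma = 0, n_frames = 30, t_bind = NA,
                       seed = 9)
  fs <- generate_trajectory(p)
  ice <- build_ice_ih(p$n_cells, p$lattice_params, seed = p$seed)
  k <- 25
  o <- frame_coords(fs, k)[water_o_idx(fs), ]
  is_ice <- fs$truth$ice_mask[, k]
  expect_gt(sum(is_ice), 50)
  expect_equal(o[is_ice, ], ice$oxygen[is_ice, ], tolerance = 1e-12)
  ## liquid-zone molecules are displaced off their sites
  liq_off <- sqrt(rowSums((o[!is_ice, ] - ice$oxygen[!is_ice, ])^2))
  expect_gt(min(liq_off), 0)
})

test_that("trajectory generation is bit-reproducible for a fixed seed", {
  p <- scripted_params(n_frames = 12, seed = 77)
  a <- generate_trajectory(p)
  b <- generate_trajectory(scripted_params(n_frames = 12, seed = 77))
  expect_identical(a$coords, b$coords)
  expect_identical(a$truth$front_z, b$truth$front_z)
})

test_that("front truncation warns when growth would leave the box", {
  p <- scripted_params(growth_rate = 3, n_frames = 60, t_bind = NA, seed = 1)
  expect_warning(fs <- generate_trajectory(p), "truncat")
  expect_lt(n_frames(fs), 60)
})

test_that("the scripted torsion schedule is realized exactly in the probe atoms", {
  p <- scripted_params(n_frames = 30, seed = 4)
  fs <- generate_trajectory(p)
  quad <- sapply(c("C1", "S1", "S2", "C2"), function(nm) atom_idx(fs, nm)[1])
  phi <- sapply(seq_len(n_frames(fs)), function(k) {
    x <- fs$coords[quad, , k]
    dihedral_angle(x[1, ], x[2, ], x[3, ], x[4, ])
  })
  expect_equal(phi, fs$truth$phi, tolerance = 1e-8)
})

test_that("ensembles carry the scripted energy order and cluster structure", {
  ens <- generate_ensemble(40, seed = 6, n_clusters = 2, within = 0.3, between = 4)
  expect_length(ens$energies, 40)
  expect_true(all(diff(ens$energies) > 0))

  cl <- ens$truth$cluster
  stopifnot(length(unique(cl)) == 2)
  pick <- function(cli, n) which(cl == cli)[seq_len(n)]
  within_r <- rmsd(ens$coords[, , pick(1, 2)[1]], ens$coords[, , pick(1, 2)[2]],
                   superpose = TRUE)
  between_r <- rmsd(ens$coords[, , pick(1, 1)[1]], ens$coords[, , pick(2, 1)[1]],
                    superpose = TRUE)
  expect_gt(between_r, within_r)

  big <- generate_ensemble(1500, seed = 2)
  expect_length(big$energies, 1500)
})

test_that("grain maps partition the image into the requested Voronoi cells", {
  one <- generate_grain_map(40, 30, 1, seed = 1)
  expect_true(all(one == 1))
  expect_equal(dim(one), c(30, 40))

  gm <- generate_grain_map(120, 90, 12, seed = 5)
  expect_true(all(gm >= 1 & gm <= 12))
  expect_setequal(as.integer(unique(as.vector(gm))), 1:12)

  ## mean grain area over all grains is exactly W*H/n when all labels appear
  st <- grain_areas(gm, exclude_border = FALSE)
  expect_equal(st$mean_area, 120 * 90 / 12)
})
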