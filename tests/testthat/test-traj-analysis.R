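test_that("front profile: boundary cases and monotone smoothing", {
  ice <- ice_333()
  wp <- classify_waters(ice$oxygen, ice$box)
  pr <- ice_front_profile(wp, ice$oxygen[, 3], ice$box[3])
  expect_equal(pr$front_z, ice$box[3])      # all ice -> box length
  expect_match(pr$diagnostic, "all ice")

  lb <- liquid_25()
  o <- frame_coords(lb, 1)[water_o_idx(lb), ]
  wpl <- classify_waters(o, lb$box)
  prl <- ice_front_profile(wpl, o[, 3], lb$box[3])
  expect_equal(prl$front_z, 0)              # no ice slab -> 0

  ## constant profile is unchanged by the monotone smoothing (occupied bins)
  occ <- !is.na(pr$profile$ice_fraction)
  expect_equal(pr$profile$monotone[occ], pr$profile$ice_fraction[occ],
               tolerance = 1e-12)
})

test_that("front tracking recovers the scripted front within a bin width", {
  p <- scripted_params(growth_rate = 0.5, sigma = 0, n_frames = 50, t_bind = NA,
                       seed = 21)
  fs <- generate_trajectory(p)
  labs <- classify_frameset(fs, frames = c(10, 30, 50))
  fr <- front_series(fs, labs)
  truth <- fs$truth$front_z[c(10, 30, 50)]
  ## the estimate sits a constant interfacial offset below the nominal line;
  ## displacements track the truth
  expect_true(all(abs(diff(fr$front_z) - diff(truth)) <= 2.5))
  expect_true(all(abs(fr$front_z - truth) <= 5))
  frc <- front_series(fs, labs, method = "count")
  expect_true(all(abs(diff(frc$front_z) - diff(truth)) <= 1.5))
})

test_that("growth rate is ~0 for a static slab and requires enough frames", {
  p <- scripted_params(growth_rate = 0, n_frames = 30, t_bind = NA, seed = 8)
  fs <- generate_trajectory(p)
  labs <- classify_frameset(fs)
  fr <- front_series(fs, labs)
  gr <- growth_rate(fr, smooth_window = 7)
  expect_lt(max(abs(gr$rate)), 0.2)
  expect_lt(abs(mean_growth_rate(fr)), 0.02)
  expect_error(growth_rate(fr[1:2, ]), "3 frames")
  expect_error(growth_rate(fr, smooth_window = 200), "window")
})

test_that("growth-rate and binding-time recovery on a scripted run", {
  fs <- traj_default()     # v = 0.5, t_bind = 60
  labs <- traj_labels()
  fr <- front_series(fs, labs, method = "count")
  rate <- mean_growth_rate(fr, c(2, 58))
  expect_lt(abs(rate - 0.5) / 0.5, 0.08)
  ## the crossing estimator agrees at the bin-width scale
  frx <- front_series(fs, labs, method = "crossing")
  expect_lt(abs(mean_growth_rate(frx, c(2, 58)) - 0.5) / 0.5, 0.15)

  cen <- solvation_census(fs, labs)
  expect_true(all(cen$n_liquid + cen$n_icelike == cen$n_total))
  tb <- detect_binding(cen)
  expect_lte(abs(tb - 60), 2)

  ## the ice-like shell population is a post-binding phenomenon
  expect_lt(mean(cen$n_icelike[cen$time < 55]), 1.5)
  expect_gte(min(cen$n_icelike[cen$time >= 61]), 4)

  ## binding slows the front: post-binding rate well below pre-binding
  post <- mean_growth_rate(fr, c(65, max(fs$times)))
  expect_lt(post, 0.5 * rate)
})

test_that("shell counts around a probe in uniform liquid match the Poisson expectation", {
  lb <- build_liquid_box(c(24, 24, 24), seed = 14)
  ## place the census probe at the box centre by appending a probe atom
  n <- nrow(lb$atoms)
  coords <- array(NA_real_, c(n + 1, 3, 1))
  coords[1:n, , 1] <- lb$coords[, , 1]
  coords[n + 1, , 1] <- lb$box / 2
  atoms <- rbind(lb$atoms, data.frame(name = "CM", element = "C", role = "probe",
                                      mol_id = max(lb$atoms$mol_id) + 1,
                                      resid = max(lb$atoms$resid) + 1,
                                      restype = "PRB"))
  fs <- frame_set(coords, atoms, lb$box, times = 0)
  labs <- classify_frameset(fs)
  cen <- solvation_census(fs, labs, r_shell = 5.4)
  expected <- 0.0334 * 4 / 3 * pi * 5.4^3
  expect_lt(abs(cen$n_total - expected), 3 * sqrt(expected))
  expect_error(solvation_census(fs, labs, r_shell = -1), "r_shell")
})

test_that("binding detection handles the degenerate censuses", {
  mk <- function(nice) {
    structure(data.frame(time = seq_along(nice) - 1, n_liquid = 10 - nice,
                         n_icelike = nice, n_total = 10),
              class = c("solvation_census", "data.frame"))
  }
  expect_equal(detect_binding(mk(rep(5, 20))), 0)            # bound from frame 0
  expect_true(is.na(detect_binding(mk(rep(0, 20)))))          # never binds
  ## a blip shorter than the dwell requirement does not count
  blip <- c(rep(0, 5), rep(6, 3), rep(0, 12))
  expect_true(is.na(detect_binding(mk(blip))))
  expect_equal(detect_binding(mk(c(rep(0, 8), rep(6, 12)))), 8)
  expect_error(detect_binding(mk(rep(5, 3))), "span")
})

test_that("torsion series recovers the schedule and omits smoothing edges", {
  fs <- traj_default()
  ts <- torsion_series(fs, smooth_window = 11)
  expect_equal(ts$phi, fs$truth$phi, tolerance = 1e-8)
  expect_true(all(is.na(ts$phi_smooth[1:5])))
  expect_true(all(is.na(ts$phi_smooth[(nrow(ts) - 4):nrow(ts)])))
  inner <- ts$phi_smooth[6:(nrow(ts) - 5)]
  expect_true(all(!is.na(inner)))
  expect_error(torsion_series(fs, c("C1", "C1", "S1", "S2")), "distinct")
})

test_that("torsion-hydration map is a normalized density with the right structure", {
  fs <- traj_default()
  labs <- traj_labels()
  cen <- solvation_census(fs, labs)
  ts <- torsion_series(fs, smooth_window = 11)
  m <- phi_hydration_map(ts, cen)
  expect_equal(sum(m$density), 1, tolerance = 1e-12)

  ## two-conformer schedule: mass on phi < 0 matches the schedule proportion
  pre <- phi_hydration_map(ts, cen, window = c(0, 59))
  neg_mass <- sum(pre$density[pre$phi_mid < 0, ])
  expect_equal(neg_mass, 30 / 60, tolerance = 0.05)

  ## constant-phi constant-count window occupies a single cell
  const <- phi_hydration_map(ts, cen, window = c(40, 50))
  expect_true(all(abs(ts$phi[ts$time >= 40 & ts$time <= 50] - 85) < 1e-9))
  expect_equal(max(const$density[const$phi_mid < 0, ]), 0)
  expect_error(phi_hydration_map(ts, cen, window = c(500, 600)), "empty")
})

test_that("hydrogen-bond criterion truth table", {
  ## donor water at origin with H pointing +x; acceptor placed per case
  mk <- function(acc_pos, h_dir = c(1, 0, 0)) {
    coords <- rbind(c(0, 0, 0),
                    h_dir / sqrt(sum(h_dir^2)) * 0.96,
                    acc_pos)
    tiny_frame(coords, names = c("OW", "HW1", "OA"),
               roles = c("water_O", "water_H", "water_O"))
  }
  count <- function(fs) {
    hb <- hydrogen_bonds(fs, donors = 1, acceptors = c(1, 3))
    sum(hb$n_ice + hb$n_other)
  }
  expect_equal(count(mk(c(2.8, 0.245, 0))), 1)   # 2.8 A, ~5 degrees
  expect_equal(count(mk(c(4.0, 0, 0))), 0)       # too far
  expect_equal(count(mk(c(1.4, 2.42, 0))), 0)    # 2.8 A but ~60 degrees
  ## a declared donor without hydrogens errors, naming the atom
  bad <- tiny_frame(rbind(c(0, 0, 0), c(2.8, 0, 0)), names = c("OX", "OA"),
                    roles = "water_O")
  expect_error(hydrogen_bonds(bad, donors = 1, acceptors = 2), "OX")
})

test_that("distance PDFs integrate to one and concentrate correctly", {
  ## rigid pair at 4.8 A
  n <- 20
  coords <- array(0, c(2, 3, n))
  coords[2, 1, ] <- 4.8
  fs <- tiny_frame(coords[, , 1], names = c("CB1", "CB2"))
  fs$coords <- coords; fs$times <- seq_len(n) - 1
  pdf <- residue_pair_pdf(fs, 1, 2)
  expect_equal(sum(pdf$density) * attr(pdf, "bin_width"), 1, tolerance = 1e-9)
  expect_equal(pdf$mid[which.max(pdf$density)], 4.8, tolerance = 0.2)

  ## scripted two-state distances: 5 A for 30% of frames, 9 A for 70%
  n <- 200
  d <- c(rep(5, 60), rep(9, 140))
  coords <- array(0, c(2, 3, n))
  coords[2, 1, ] <- d
  fs2 <- tiny_frame(coords[, , 1], names = c("CB1", "CB2"))
  fs2$coords <- coords; fs2$times <- seq_len(n) - 1
  pdf2 <- residue_pair_pdf(fs2, 1, 2, bin_width = 0.2)
  mass_near <- function(x) sum(pdf2$density[abs(pdf2$mid - x) < 0.5]) * 0.2
  expect_equal(mass_near(5), 0.3, tolerance = 0.01)
  expect_equal(mass_near(9), 0.7, tolerance = 0.01)
  expect_error(residue_pair_pdf(fs2, 1, 2, window = c(1e6, 2e6)), "empty")
})

test_that("RMSD series is zero against itself and for rigid motions", {
  fs <- traj_default()
  probe <- which(fs$atoms$role == "probe")
  rs <- rmsd_series(fs, probe, reference = 1, superpose = TRUE)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-10)

  ## a rigidly moved copy of frame 1 superposes to ~0
  x <- fs$coords[probe, , 1]
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- sweep(x %*% rot, 2, c(5, 5, 5), "+")
  expect_lt(rmsd(moved, x, superpose = TRUE), 1e-6)
  expect_error(rmsd_series(fs, probe[1:2]), "3 atoms")
})
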