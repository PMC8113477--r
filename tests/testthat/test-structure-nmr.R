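test_that("C-beta shifts classify redox states with the documented thresholds", {
  tab <- packaged_shift_table()
  res <- classify_cys_redox(tab)
  calls <- res$calls
  expect_equal(calls$state[calls$position == 13], "oxidized")   # 42.07 ppm
  expect_equal(calls$state[calls$position == 3], "oxidized")    # 38.84 ppm
  expect_equal(calls$state[calls$position == 2], "reduced")     # 28.13 ppm
  expect_equal(calls$state[calls$position == 7], "reduced")     # 28.12 ppm
  expect_equal(res$inferred_pair, c(3, 13))

  mid <- data.frame(position = 3, res = "C", atom = "CB", ppm = 33.5)
  expect_equal(classify_cys_redox(mid)$calls$state, "indeterminate")
  expect_error(classify_cys_redox(data.frame(position = 1, res = "T",
                                             atom = "CB", ppm = 69)), "cysteine")
})

test_that("redox classifier is monotone in the shift", {
  grid <- seq(20, 50, by = 0.5)
  states <- vapply(grid, function(p) {
    classify_cys_redox(data.frame(position = 2, res = "C", atom = "CB",
                                  ppm = p))$calls$state
  }, "")
  lvl <- c(reduced = 1, indeterminate = 2, oxidized = 3)
  expect_true(all(diff(lvl[states]) >= 0))
})

test_that("ensemble ranking shortlists k models and finds the planted representative", {
  ens <- generate_ensemble(300, seed = 17, planted_best = TRUE)
  rk <- rank_ensemble(ens, k = 10)
  expect_equal(nrow(rk$shortlist), 10)
  expect_setequal(rk$shortlist$model, order(ens$energies)[1:10])
  expect_equal(rk$representative, ens$truth$planted)
  ## RMSD matrix is symmetric with a zero diagonal
  expect_equal(rk$rmsd_matrix, t(rk$rmsd_matrix))
  expect_true(all(diag(rk$rmsd_matrix) == 0))
  expect_error(rank_ensemble(ens, k = 0), "k")
  expect_error(rank_ensemble(ens, k = 301), "k")
})

test_that("ranking is invariant to model input order", {
  ens <- generate_ensemble(60, seed = 23)
  rk1 <- rank_ensemble(ens, k = 8)
  perm <- withr::with_seed(1, sample(60))
  shuf <- ens
  shuf$coords <- ens$coords[, , perm]
  shuf$energies <- ens$energies[perm]
  rk2 <- rank_ensemble(shuf, k = 8)
  ## map the shuffled representative back to original ids
  expect_equal(perm[rk2$representative], rk1$representative)
  expect_equal(sort(perm[rk2$shortlist$model]), sort(rk1$shortlist$model))
})

test_that("exact rank-sum ties break toward the lower energy", {
  ## two identical-coordinate models: identical mean RMSD, distinct energies
  ens <- generate_ensemble(2, seed = 1, within = 0, between = 0,
                           planted_best = FALSE, n_clusters = 1,
                           energies = c(-5, 3))
  rk <- rank_ensemble(ens, k = 2)
  expect_equal(rk$representative, 1)
})

test_that("C-beta distances behave and refuse glycine", {
  ens <- generate_ensemble(3, seed = 2)
  d <- cbeta_distance(ens, 1, 10, 14)
  expect_equal(d, cbeta_distance(ens, 1, 14, 10))
  expect_gt(d, 0)
  expect_error(cbeta_distance(ens, 1, 5, 10), "C-beta")   # Gly placeholder

  ## constructed model with CB atoms exactly 4.8 A apart
  ens2 <- ens
  i10 <- which(ens2$atoms$resid == 10 & ens2$atoms$name == "CB")
  i14 <- which(ens2$atoms$resid == 14 & ens2$atoms$name == "CB")
  ens2$coords[i10, , 1] <- c(0, 0, 0)
  ens2$coords[i14, , 1] <- c(4.8, 0, 0)
  expect_equal(cbeta_distance(ens2, 1, 10, 14), 4.8)

  ## coincident atoms give zero
  ens2$coords[i14, , 1] <- c(0, 0, 0)
  expect_equal(cbeta_distance(ens2, 1, 10, 14), 0)
})

test_that("pairwise distance range spans the shortlist values", {
  ens <- generate_ensemble(3, seed = 2)
  i10 <- which(ens$atoms$resid == 10 & ens$atoms$name == "CB")
  i14 <- which(ens$atoms$resid == 14 & ens$atoms$name == "CB")
  ens$coords[i10, , ] <- 0
  ens$coords[i14, , 1] <- c(6.4, 0, 0)
  ens$coords[i14, , 2] <- c(12.4, 0, 0)
  ens$coords[i14, , 3] <- c(0, 9, 0)
  rng <- pairwise_distance_range(ens, 1:3, 10, 14)
  expect_equal(unname(rng), c(6.4, 12.4))
  d_each <- vapply(1:3, function(m) cbeta_distance(ens, m, 10, 14), 0)
  expect_true(all(d_each >= rng["min"] & d_each <= rng["max"]))
  expect_equal(unname(pairwise_distance_range(ens, 2, 10, 14)),
               c(12.4, 12.4))
  expect_error(pairwise_distance_range(ens, integer(), 10, 14), "empty")
})
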