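## Synthetic conformer ensembles with known energy ranking and controlled
## pairwise-RMSD cluster structure, standing in for chemical-shift-guided
## structure-calculation output (model coordinates of the real peptide are
## not available).

## Synthetic cyclic backbone for the 14-residue scaffold: CA atoms on a ring,
## CB atoms pointing outward for non-Gly residues.
scaffold_backbone <- function(scaffold = build_canonical_scaffold(), radius = 6.5) {
  nres <- length(scaffold$residues)
  ang <- 2 * pi * (seq_len(nres) - 1) / nres
  ca <- cbind(radius * cos(ang), radius * sin(ang), 0.8 * sin(2 * ang))
  atoms <- data.frame(name = "CA", element = "C", role = "peptide",
                      mol_id = 1L, resid = seq_len(nres),
                      restype = scaffold$residues)
  coords <- ca
  for (i in seq_len(nres)) {
    if (scaffold$residues[i] != "G") {
      dir <- c(cos(ang[i]), sin(ang[i]), 0)
      coords <- rbind(coords, ca[i, ] + 1.53 * dir)
      atoms <- rbind(atoms, data.frame(name = "CB", element = "C",
                                       role = "peptide", mol_id = 1L,
                                       resid = i, restype = scaffold$residues[i]))
    }
  }
  list(atoms = atoms, coords = coords)
}

#' Generate a synthetic conformer ensemble
#'
#' Models are built from a common synthetic cyclic backbone, displaced by
#' per-cluster coordinate fields (controlling between-cluster RMSD) plus
#' per-model noise (within-cluster RMSD), then placed at random rigid-body
#' orientations. Energies increase strictly with model index, so the energy
#' ranking is known by construction. With `planted_best = TRUE`, model 1 has
#' the lowest energy, sits exactly at the centre of the majority cluster of
#' the low-energy shortlist, and is therefore the planted representative.
#'
#' @param n_models number of models (>= 1).
#' @param seed integer seed.
#' @param energies explicit energy vector, or NULL for an increasing sequence
#'   spanning `energy_range`.
#' @param energy_range length-2 range used when `energies` is NULL.
#' @param n_clusters number of RMSD clusters.
#' @param within within-cluster per-atom noise SD, Angstrom.
#' @param between between-cluster displacement-field SD, Angstrom.
#' @param planted_best plant model 1 as the dominant representative.
#' @param scaffold scaffold used for the backbone and atom table.
#' @return a `conformer_ensemble`: `atoms`, `coords`
#'   (n_atoms x 3 x n_models), `energies`, and `truth` (cluster assignment,
#'   planted model id).
#' @export
generate_ensemble <- function(n_models, seed = 1L, energies = NULL,
                              energy_range = c(-20, 30), n_clusters = 2,
                              within = 0.4, between = 4.0,
                              planted_best = TRUE,
                              scaffold = build_canonical_scaffold()) {
  stopifnot(n_models >= 1)
  bb <- scaffold_backbone(scaffold)
  na <- nrow(bb$coords)
  if (is.null(energies)) {
    energies <- seq(energy_range[1], energy_range[2], length.out = n_models)
  }
  stopifnot(length(energies) == n_models)
  with_seed(seed, {
    centers <- lapply(seq_len(n_clusters), function(cl) {
      matrix(stats::rnorm(na * 3, sd = between), na, 3)
    })
    cluster <- sample.int(n_clusters, n_models, replace = TRUE)
    if (planted_best) {
      ## the 10-model low-energy shortlist is dominated by cluster 1, with
      ## model 1 exactly at its centre
      k0 <- min(10L, n_models)
      n_maj <- max(1L, ceiling(k0 * 0.7))
      cluster[seq_len(n_maj)] <- 1L
      if (n_clusters > 1 && k0 > n_maj) {
        cluster[(n_maj + 1):k0] <- rep(seq(2L, n_clusters), length.out = k0 - n_maj)
      }
    }
    coords <- array(NA_real_, c(na, 3, n_models))
    for (m in seq_len(n_models)) {
      noise <- if (planted_best && m == 1L) 0 else
        matrix(stats::rnorm(na * 3, sd = within), na, 3)
      x <- bb$coords + centers[[cluster[m]]] + noise
      x <- x %*% random_rotation()
      x <- sweep(x, 2, stats::runif(3, -20, 20), "+")
      coords[, , m] <- x
    }
    structure(list(
      atoms = bb$atoms, coords = coords, energies = as.numeric(energies),
      model_ids = seq_len(n_models),
      truth = list(cluster = cluster,
                   planted = if (planted_best) 1L else NA_integer_)
    ), class = "conformer_ensemble")
  })
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d models x %d atoms, energies %.2f..%.2f\n",
              length(x$energies), nrow(x$atoms),
              min(x$energies), max(x$energies)))
  invisible(x)
}
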