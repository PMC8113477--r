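## Proton-disordered hexagonal ice (ice Ih) lattice generator.
##
## Oxygens sit on a lonsdaleite (hexagonal diamond) lattice expressed in an
## orthorhombic cell of 8 molecules; protons are placed randomly on the O-O
## bond network and repaired to Bernal-Fowler validity (each oxygen owns
## exactly two hydrogens, each hydrogen bond carries exactly one) by
## zero-temperature defect-annihilating Monte Carlo moves.

#' Build a proton-disordered ice Ih lattice
#'
#' @param n_cells integer triple `(nx, ny, nz)`: repeats of the 8-molecule
#'   orthorhombic cell along x, y (basal plane) and z (c-axis).
#' @param lattice_params list with hexagonal lattice constants `a` and `c` in
#'   Angstrom; defaults `a = 4.50`, `c = 7.34` (standard ice Ih near 265 K).
#' @param seed integer seed for the proton placement.
#' @param oh_length O-H bond length along the hydrogen bond, Angstrom.
#' @param max_iter Monte Carlo move budget for the Bernal-Fowler repair.
#' @return an `ice_lattice`: oxygen and hydrogen coordinate matrices (Angstrom),
#'   the orthorhombic `box`, the O-O `bonds` data.frame (columns `i`, `j`,
#'   `owner` giving which oxygen donates the hydrogen on that bond), and
#'   `lattice_params`.
#' @examples
#' ice <- build_ice_ih(c(2, 2, 2), seed = 1)
#' nrow(ice$oxygen)    # 64 molecules
#' bernal_fowler_violations(ice)  # 0
#' @export
build_ice_ih <- function(n_cells = c(3, 3, 3),
                         lattice_params = list(a = 4.50, c = 7.34),
                         seed = 1L, oh_length = 1.0, max_iter = 1e6) {
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 3 || any(n_cells < 1)) stop("n_cells must be three integers >= 1")
  a <- lattice_params$a
  cc <- lattice_params$c
  box <- c(n_cells[1] * a, n_cells[2] * sqrt(3) * a, n_cells[3] * cc)

  ## 8 oxygens of the orthorhombic cell: two interpenetrating hcp sublattices
  ## offset by 3c/8 along z, replicated at the in-plane hex translation.
  base4 <- rbind(
    c(0, 0, 0),
    c(0, a / sqrt(3), cc / 2),
    c(0, 0, 3 * cc / 8),
    c(0, a / sqrt(3), 7 * cc / 8)
  )
  cell8 <- rbind(base4, sweep(base4, 2, c(a / 2, sqrt(3) * a / 2, 0), "+"))

  shifts <- as.matrix(expand.grid(
    x = (seq_len(n_cells[1]) - 1) * a,
    y = (seq_len(n_cells[2]) - 1) * sqrt(3) * a,
    z = (seq_len(n_cells[3]) - 1) * cc
  ))
  oxy <- do.call(rbind, lapply(seq_len(nrow(shifts)),
                               function(s) sweep(cell8, 2, shifts[s, ], "+")))
  oxy <- wrap_box(oxy, box)

  bonds <- oo_bond_list(oxy, box)
  owner <- with_seed(seed, bf_repair(bonds, nrow(oxy), max_iter = max_iter))
  bonds$owner <- owner

  hyd <- place_protons(oxy, bonds, box, oh_length)
  structure(
    list(oxygen = oxy, hydrogen = hyd, box = box, bonds = bonds,
         lattice_params = list(a = a, c = cc), n_cells = n_cells,
         oh_length = oh_length),
    class = "ice_lattice"
  )
}

## O-O adjacency from the nearest-neighbor shell (cutoff halfway to the
## second shell). Bonds are enumerated per periodic image so that small
## cells, where one pair of molecules can be bonded through two different
## images, still yield the full 4-regular bond multigraph.
oo_bond_list <- function(oxy, box, cutoff = 3.2) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  out <- vector("list", nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ] * box
    d <- pair_dist(oxy, sweep(oxy, 2, sh, "+"))
    idx <- which(d < cutoff & upper.tri(d, diag = FALSE), arr.ind = TRUE)
    if (nrow(idx)) {
      out[[s]] <- data.frame(i = unname(idx[, 1]), j = unname(idx[, 2]),
                             sx = unname(shifts[s, 1]), sy = unname(shifts[s, 2]),
                             sz = unname(shifts[s, 3]))
    }
  }
  do.call(rbind, out)
}

## Zero-temperature Monte Carlo repair of the random proton assignment:
## repeatedly move the hydrogen of a random bond from one end to the other
## when that does not increase the total squared deviation of per-oxygen
## donor counts from two. Defects random-walk and annihilate pairwise.
bf_repair <- function(bonds, n_oxy, max_iter = 1e6) {
  nb <- nrow(bonds)
  owner <- ifelse(stats::runif(nb) < 0.5, bonds$i, bonds$j)
  own <- tabulate(owner, nbins = n_oxy)
  defect <- sum((own - 2L)^2)
  it <- 0L
  check_every <- 5000L
  while (defect > 0 && it < max_iter) {
    for (k in seq_len(check_every)) {
      b <- sample.int(nb, 1L)
      o <- owner[b]
      t <- if (o == bonds$i[b]) bonds$j[b] else bonds$i[b]
      delta <- (own[o] - 3L)^2 + (own[t] - 1L)^2 - (own[o] - 2L)^2 - (own[t] - 2L)^2
      if (delta <= 0L) {
        owner[b] <- t
        own[o] <- own[o] - 1L
        own[t] <- own[t] + 1L
        defect <- defect + delta
      }
    }
    it <- it + check_every
  }
  if (defect > 0) {
    stop("Bernal-Fowler repair did not converge within the iteration budget",
         call. = FALSE)
  }
  owner
}

## One hydrogen per bond, placed on the owning oxygen along the bond's own
## periodic image direction.
place_protons <- function(oxy, bonds, box, oh_length) {
  from <- oxy[bonds$owner, , drop = FALSE]
  sh <- as.matrix(bonds[, c("sx", "sy", "sz")]) * rep(box, each = nrow(bonds))
  to_i <- bonds$owner == bonds$i
  other <- ifelse(to_i, bonds$j, bonds$i)
  to <- oxy[other, , drop = FALSE] + ifelse(to_i, 1, -1) * sh
  h <- from + row_normalize(to - from) * oh_length
  wrap_box(h, box)
}

#' Audit the Bernal-Fowler ice rules
#'
#' Brute-force rule check over every oxygen and every O-O bond: each oxygen
#' must donate exactly two hydrogens, each bond must carry exactly one, and
#' the hydrogen count must be twice the oxygen count.
#'
#' @param ice an `ice_lattice`.
#' @return integer count of violations (0 for a valid lattice).
#' @export
bernal_fowler_violations <- function(ice) {
  stopifnot(inherits(ice, "ice_lattice"))
  own <- tabulate(ice$bonds$owner, nbins = nrow(ice$oxygen))
  v <- sum(own != 2L)
  ## each bond carries exactly one H: owner must be one of its two ends
  v <- v + sum(!(ice$bonds$owner == ice$bonds$i | ice$bonds$owner == ice$bonds$j))
  v <- v + as.integer(nrow(ice$hydrogen) != 2L * nrow(ice$oxygen))
  v
}

#' @export
print.ice_lattice <- function(x, ...) {
  cat(sprintf(
    "<ice_lattice> %d H2O (proton-disordered Ih), box %.2f x %.2f x %.2f A, a=%.2f c=%.2f\n",
    nrow(x$oxygen), x$box[1], x$box[2], x$box[3],
    x$lattice_params$a, x$lattice_params$c))
  invisible(x)
}
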