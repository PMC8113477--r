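## Local bond-order classification of water molecules (CHILL+-style).
##
## Each water oxygen gets a local l=3 Steinhardt vector built from the bond
## directions to its four nearest neighbors; the normalized correlation c_ij
## of the vectors on the two ends of a hydrogen bond distinguishes staggered
## (ice-like, c near -1) from eclipsed (c in a band around 0) bonds, and the
## per-molecule counts of staggered/eclipsed bonds decide the phase label:
## hexagonal ice, cubic ice, interfacial ice, clathrate, interfacial
## clathrate, or liquid.

PHASE_LEVELS <- c("HEX", "CUBIC", "INT_ICE", "CLATH", "INT_CLATH", "LIQ")

#' Default classification cutoffs
#'
#' Staggered bonds have c_ij at or below `staggered`; eclipsed bonds fall in
#' the `eclipsed` band. Neighbors are the four nearest oxygens within `r_cut`;
#' molecules with fewer than four neighbors inside the cutoff are labelled
#' liquid by fiat (surface/gas safety).
#'
#' @param staggered upper bound on c_ij for a staggered bond (default -0.8).
#' @param eclipsed length-2 band for an eclipsed bond (default c(-0.35, 0.25)).
#' @param r_cut neighbor cutoff in Angstrom (default 3.5).
#' @export
phase_cutoffs <- function(staggered = -0.8, eclipsed = c(-0.35, 0.25), r_cut = 3.5) {
  stopifnot(length(eclipsed) == 2, eclipsed[1] < eclipsed[2])
  list(staggered = staggered, eclipsed = eclipsed, r_cut = r_cut)
}

## Complex spherical harmonics Y_3m (Condon-Shortley), m = -3..3, evaluated
## on unit vectors given as an n x 3 matrix. Returns an n x 7 complex matrix.
y3_components <- function(u) {
  z <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  s <- sqrt(pmax(0, 1 - z^2))
  e1 <- exp(1i * phi); e2 <- e1 * e1; e3 <- e2 * e1
  y0 <- sqrt(7 / (16 * pi)) * (5 * z^3 - 3 * z)
  f1 <- (1 / 8) * sqrt(21 / pi) * s * (5 * z^2 - 1)
  f2 <- (1 / 4) * sqrt(105 / (2 * pi)) * s^2 * z
  f3 <- (1 / 8) * sqrt(35 / pi) * s^3
  cbind(
    f3 * Conj(e3),        # m = -3
    f2 * Conj(e2),        # m = -2
    f1 * Conj(e1),        # m = -1
    y0 + 0i,              # m =  0
    -f1 * e1,             # m = +1
    f2 * e2,              # m = +2
    -f3 * e3              # m = +3
  )
}

#' Local l=3 bond-order vector
#'
#' q3m(i) = (1/N_b) sum_j Y_3m(r_ij hat) over the neighbors j of molecule i.
#'
#' @param center length-3 coordinate of the central oxygen.
#' @param neighbors matrix of neighbor coordinates (rows).
#' @param box optional orthorhombic box for minimum-image bond vectors.
#' @return complex vector of 7 components (m = -3..3).
#' @export
q3_vector <- function(center, neighbors, box = NULL) {
  neighbors <- rbind(neighbors)
  if (nrow(neighbors) < 1) stop("q3 needs at least one neighbor", call. = FALSE)
  dx <- sweep(neighbors, 2, as.numeric(center), "-")
  if (!is.null(box)) dx <- min_image(dx, box)
  u <- row_normalize(dx)
  colMeans(y3_components(u))
}

#' Bond-order correlation between two molecules
#'
#' c_ij = Re(sum_m q3m(i) conj(q3m(j))) / (|q3(i)| |q3(j)|), in [-1, 1].
#'
#' @param q3_i,q3_j complex length-7 q3 vectors.
#' @export
bond_correlation <- function(q3_i, q3_j) {
  ni <- sqrt(Re(sum(q3_i * Conj(q3_i))))
  nj <- sqrt(Re(sum(q3_j * Conj(q3_j))))
  if (ni == 0 || nj == 0) stop("q3 vector has zero norm", call. = FALSE)
  Re(sum(q3_i * Conj(q3_j))) / (ni * nj)
}

#' Classify water molecules into ice/clathrate/liquid phases
#'
#' Implements the bond-counting rules on the four nearest-neighbor bonds of
#' each molecule: 4 staggered = cubic ice; 3 staggered + 1 eclipsed =
#' hexagonal ice; 4 eclipsed = clathrate; exactly 3 eclipsed = interfacial
#' clathrate; otherwise >= 2 staggered = interfacial ice; anything else is
#' liquid. Molecules with fewer than four neighbors within the cutoff are
#' liquid by fiat.
#'
#' @param coords n x 3 matrix of water-oxygen coordinates (Angstrom).
#' @param box orthorhombic box lengths (minimum-image distances), or NULL for
#'   open boundaries.
#' @param cutoffs a [phase_cutoffs()] list.
#' @return a `water_phase_labels` object: `label` (factor over the six
#'   phases), `n_staggered`, `n_eclipsed`, the per-molecule neighbor index
#'   matrix, and the bond table with c_ij values.
#' @export
classify_waters <- function(coords, box = NULL, cutoffs = phase_cutoffs()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  empty <- function(reason) {
    structure(list(
      label = factor(rep("LIQ", n), levels = PHASE_LEVELS),
      n_staggered = rep(NA_integer_, n), n_eclipsed = rep(NA_integer_, n),
      neighbors = matrix(NA_integer_, n, 4),
      bonds = data.frame(i = integer(), j = integer(), c = numeric()),
      cutoffs = cutoffs, diagnostic = reason
    ), class = "water_phase_labels")
  }
  if (n < 4) {
    if (n > 0) message("fewer than 4 molecules; all labelled LIQ")
    return(empty("fewer than 4 molecules"))
  }

  d <- pair_dist(coords, box = box)
  diag(d) <- Inf

  ## up to 4 nearest neighbors within the cutoff, per molecule; four passes
  ## of max.col on the negated distance matrix avoid a per-row sort
  nbr4 <- matrix(NA_integer_, n, 4)
  d4 <- matrix(NA_real_, n, 4)
  dw <- -d
  for (pass in 1:4) {
    j <- max.col(dw, ties.method = "first")
    nbr4[, pass] <- j
    d4[, pass] <- d[cbind(seq_len(n), j)]
    dw[cbind(seq_len(n), j)] <- -Inf
  }
  within <- d4 <= cutoffs$r_cut
  nnb <- as.integer(rowSums(within))
  nbr <- nbr4
  nbr[!within] <- NA_integer_

  ## q3 for every molecule with at least one neighbor
  bi <- rep(seq_len(n), nnb)
  bj <- as.integer(t(nbr))[!is.na(as.integer(t(nbr)))]
  q3 <- matrix(0 + 0i, n, 7)
  if (length(bi)) {
    dx <- coords[bj, , drop = FALSE] - coords[bi, , drop = FALSE]
    if (!is.null(box)) dx <- min_image(dx, box)
    y <- y3_components(row_normalize(dx))
    ids <- sort(unique(bi))
    re <- rowsum(Re(y), bi)
    im <- rowsum(Im(y), bi)
    q3[ids, ] <- re + 1i * im
    q3 <- q3 / pmax(nnb, 1)
  }
  nrm <- sqrt(Re(rowSums(q3 * Conj(q3))))

  ## c_ij on the 4 bonds of fully coordinated molecules
  full <- which(nnb == 4L)
  ci <- rep(full, each = 4)
  cj <- as.integer(t(nbr[full, , drop = FALSE]))
  cval <- rep(NA_real_, length(ci))
  okn <- nrm[ci] > 0 & nrm[cj] > 0
  if (any(okn)) {
    num <- Re(rowSums(q3[ci[okn], , drop = FALSE] * Conj(q3[cj[okn], , drop = FALSE])))
    cval[okn] <- num / (nrm[ci[okn]] * nrm[cj[okn]])
  }

  stag <- !is.na(cval) & cval <= cutoffs$staggered
  ecl <- !is.na(cval) & cval >= cutoffs$eclipsed[1] & cval <= cutoffs$eclipsed[2]
  n_stag <- integer(n); n_ecl <- integer(n)
  if (length(ci)) {
    ts <- tapply(stag, ci, sum); te <- tapply(ecl, ci, sum)
    n_stag[as.integer(names(ts))] <- as.integer(ts)
    n_ecl[as.integer(names(te))] <- as.integer(te)
  }

  lab <- rep("LIQ", n)
  isf <- seq_len(n) %in% full
  lab[isf & n_stag == 4] <- "CUBIC"
  lab[isf & n_stag == 3 & n_ecl == 1] <- "HEX"
  lab[isf & lab == "LIQ" & n_ecl == 4] <- "CLATH"
  lab[isf & lab == "LIQ" & n_ecl == 3] <- "INT_CLATH"
  lab[isf & lab == "LIQ" & n_stag >= 2] <- "INT_ICE"

  structure(list(
    label = factor(lab, levels = PHASE_LEVELS),
    n_staggered = n_stag, n_eclipsed = n_ecl,
    neighbors = nbr,
    bonds = data.frame(i = ci, j = cj, c = cval),
    cutoffs = cutoffs, diagnostic = NULL
  ), class = "water_phase_labels")
}

#' @export
print.water_phase_labels <- function(x, ...) {
  cat("<water_phase_labels>", length(x$label), "waters\n")
  print(table(x$label))
  invisible(x)
}

#' Is a label ice-like?
#'
#' Ice-like is hexagonal, cubic or interfacial ice; this grouping backs the
#' liquid-vs-ice solvation-shell census and the front profile. The grouping
#' is a configuration choice, exposed here so alternatives can be audited.
#'
#' @param label factor/character vector of phase labels.
#' @param include_interfacial count interfacial ice as ice-like (default TRUE).
#' @export
ice_like <- function(label, include_interfacial = TRUE) {
  lv <- c("HEX", "CUBIC", if (include_interfacial) "INT_ICE")
  as.character(label) %in% lv
}

#' Clathrate-like fraction of a solvation shell
#'
#' Fraction of water oxygens within `r` of any of the probe atoms whose label
#' is clathrate or interfacial clathrate. An empty shell is reported as NA
#' (undefined), not 0.
#'
#' @param labels a `water_phase_labels` for the frame.
#' @param coords water-oxygen coordinates the labels refer to.
#' @param around coordinates (matrix of rows) of the probe atoms.
#' @param r shell radius, Angstrom (> 0).
#' @param box orthorhombic box or NULL.
#' @export
clathrate_fraction <- function(labels, coords, around, r, box = NULL) {
  stopifnot_scalar_number(r, "r", positive = TRUE)
  d <- pair_dist(as.matrix(coords), rbind(around), box = box)
  shell <- which(apply(d, 1, min) <= r)
  if (!length(shell)) return(NA_real_)
  mean(as.character(labels$label[shell]) %in% c("CLATH", "INT_CLATH"))
}
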