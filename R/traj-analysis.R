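## Trajectory analysis stack: per-frame phase labels, ice-front tracking and
## growth rate, solvation-shell census, binding detection, disulfide torsion
## series, torsion-hydration maps, hydrogen bonds, residue-pair distance
## distributions, and RMSD series.

#' Classify the waters of every frame
#'
#' @param fs a `frame_set`.
#' @param frames frame indices (default all).
#' @param cutoffs a [phase_cutoffs()] list.
#' @return list of `water_phase_labels`, one per requested frame, with the
#'   water-oxygen atom indices attached as an attribute.
#' @export
classify_frameset <- function(fs, frames = seq_len(n_frames(fs)),
                              cutoffs = phase_cutoffs()) {
  widx <- water_o_idx(fs)
  box <- effective_box(fs)
  out <- lapply(frames, function(k) {
    classify_waters(fs$coords[widx, , k], box, cutoffs)
  })
  attr(out, "water_idx") <- widx
  attr(out, "frames") <- frames
  out
}

#' Ice-front position from a labelled frame
#'
#' Bins the slab along z, computes the ice-like fraction per bin, enforces a
#' monotone (non-increasing away from the ice side) profile to suppress
#' single-bin noise, and reports the linearly interpolated z at which the
#' fraction crosses 0.5, scanning from the ice side (low z).
#'
#' @param labels a `water_phase_labels` for the frame.
#' @param z z coordinates of the water oxygens the labels refer to.
#' @param z_len slab extent along z (box length), Angstrom.
#' @param bin_width z bin width, Angstrom (default 1.5).
#' @return list: `front_z`, the per-bin `profile` data.frame (bin center, raw
#'   and monotone ice fraction), and a `diagnostic` when the profile never
#'   crosses 0.5 (all ice or all liquid; the boundary value is returned).
#' @export
ice_front_profile <- function(labels, z, z_len, bin_width = 1.5) {
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  breaks <- seq(0, z_len, by = bin_width)
  if (breaks[length(breaks)] < z_len) breaks <- c(breaks, z_len)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  il <- ice_like(labels$label)
  bin <- findInterval(z %% z_len, breaks, rightmost.closed = TRUE)
  frac <- vapply(seq_along(mids), function(b) {
    n <- sum(bin == b)
    if (n == 0) NA_real_ else mean(il[bin == b])
  }, 0)
  ## empty bins (gaps between crystal layers) inherit the last value seen
  ## scanning up from the ice side
  frac_f <- frac
  last <- 0
  for (b in seq_along(frac_f)) {
    if (is.na(frac_f[b])) frac_f[b] <- last else last <- frac_f[b]
  }
  mono <- rev(cummax(rev(frac_f)))   # non-increasing towards high z

  diagnostic <- NULL
  if (all(mono >= 0.5)) {
    front <- z_len
    diagnostic <- "profile never drops below 0.5 (all ice)"
  } else if (mono[1] < 0.5) {
    front <- 0
    diagnostic <- "profile starts below 0.5 (no ice slab)"
  } else {
    b <- which(mono < 0.5)[1]        # first bin past the crossing
    z1 <- mids[b - 1]; z2 <- mids[b]
    f1 <- mono[b - 1]; f2 <- mono[b]
    front <- z1 + (f1 - 0.5) / (f1 - f2) * (z2 - z1)
  }
  list(front_z = front,
       profile = data.frame(z = mids, ice_fraction = frac, monotone = mono),
       diagnostic = diagnostic)
}

#' Ice-front series over a trajectory
#'
#' Two estimators are available. `"crossing"` takes the per-frame 0.5
#' crossing of the binned ice-fraction profile ([ice_front_profile()]); it
#' localizes the interface within a bin but inherits interface-conversion
#' noise. `"count"` divides the total ice-like population by the areal
#' molecule density per unit z, i.e. an integral estimator whose *changes*
#' track front displacement with far less noise (the constant labelling
#' offset of interfacial layers cancels in differences); it is the better
#' input for growth-rate estimation on slow fronts.
#'
#' @param fs a `frame_set` in slab geometry (ice at low z).
#' @param labels_list per-frame labels from [classify_frameset()].
#' @param bin_width z bin width for the crossing estimator, Angstrom.
#' @param method `"crossing"` or `"count"`.
#' @return a `front_series` data.frame: `time` (ns), `front_z` and `growth`
#'   (displacement relative to frame 1), both Angstrom.
#' @export
front_series <- function(fs, labels_list, bin_width = 1.5,
                         method = c("crossing", "count")) {
  method <- match.arg(method)
  widx <- attr(labels_list, "water_idx") %||% water_o_idx(fs)
  frames <- attr(labels_list, "frames") %||% seq_along(labels_list)
  fz <- if (method == "crossing") {
    vapply(seq_along(labels_list), function(ii) {
      k <- frames[ii]
      ice_front_profile(labels_list[[ii]], fs$coords[widx, 3, k],
                        fs$box[3], bin_width)$front_z
    }, 0)
  } else {
    rho <- length(widx) / fs$box[3]   # molecules per Angstrom of slab height
    vapply(labels_list, function(l) sum(ice_like(l$label)) / rho, 0)
  }
  out <- data.frame(time = fs$times[frames], front_z = fz, growth = fz - fz[1])
  class(out) <- c("front_series", "data.frame")
  out
}

#' Growth rate of the ice front
#'
#' Centered finite difference of the moving-average-smoothed front position
#' with respect to time, in Angstrom/ns. Edges where the smoothing window
#' does not fit are omitted.
#'
#' @param front a `front_series`.
#' @param smooth_window moving-average window, points (odd; default 11).
#' @return data.frame `time`, `rate` restricted to frames where both the
#'   smoothing window and the centered difference are defined.
#' @export
growth_rate <- function(front, smooth_window = 11) {
  n <- nrow(front)
  if (n < 3) stop("growth rate needs at least 3 frames", call. = FALSE)
  if (smooth_window > n) stop("smoothing window exceeds series length", call. = FALSE)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  sm <- as.numeric(stats::filter(front$front_z, rep(1 / w, w), sides = 2))
  rate <- rep(NA_real_, n)
  for (k in seq(2, n - 1)) {
    if (!is.na(sm[k - 1]) && !is.na(sm[k + 1])) {
      rate[k] <- (sm[k + 1] - sm[k - 1]) / (front$time[k + 1] - front$time[k - 1])
    }
  }
  ok <- !is.na(rate)
  data.frame(time = front$time[ok], rate = rate[ok])
}

#' Mean growth rate over a time window
#'
#' Least-squares slope of the front position against time over the window;
#' more robust than averaging the pointwise derivative when the front
#' advances in discrete lattice-layer steps.
#'
#' @param front a `front_series`.
#' @param window length-2 time span in ns (default: the full series).
#' @return slope in Angstrom/ns.
#' @export
mean_growth_rate <- function(front, window = range(front$time)) {
  sel <- front$time >= window[1] & front$time <= window[2]
  if (sum(sel) < 2) stop("window contains fewer than 2 frames", call. = FALSE)
  unname(stats::coef(stats::lm(front_z ~ time, data = front[sel, ]))[2])
}

#' Solvation-shell census around a probe atom
#'
#' Counts, per frame, the water oxygens within `r_shell` of the probe atom,
#' split into ice-like (hexagonal, cubic or interfacial ice) and liquid
#' (everything else, including clathrate-like labels). The default shell
#' radius 5.4 A is the first minimum of a methane-water pair correlation,
#' appropriate for a methyl-carbon probe.
#'
#' @param fs a `frame_set`.
#' @param labels_list per-frame labels from [classify_frameset()].
#' @param probe_atom atom index, or an atom name resolved against the probe
#'   role (default `"CM"`, the methyl carbon of scripted trajectories).
#' @param r_shell shell radius, Angstrom (> 0).
#' @return a `solvation_census` data.frame: `time`, `n_liquid`, `n_icelike`,
#'   `n_total`.
#' @export
solvation_census <- function(fs, labels_list, probe_atom = "CM", r_shell = 5.4) {
  stopifnot_scalar_number(r_shell, "r_shell", positive = TRUE)
  if (is.character(probe_atom)) {
    probe_atom <- atom_idx(fs, probe_atom)[1]
    if (is.na(probe_atom)) stop("probe atom not found", call. = FALSE)
  }
  widx <- attr(labels_list, "water_idx") %||% water_o_idx(fs)
  frames <- attr(labels_list, "frames") %||% seq_along(labels_list)
  box <- effective_box(fs)
  out <- do.call(rbind, lapply(seq_along(labels_list), function(ii) {
    k <- frames[ii]
    d <- pair_dist(fs$coords[widx, , k, drop = TRUE],
                   matrix(fs$coords[probe_atom, , k], 1), box = box)
    shell <- d[, 1] <= r_shell
    il <- ice_like(labels_list[[ii]]$label) & shell
    data.frame(time = fs$times[k], n_liquid = sum(shell) - sum(il),
               n_icelike = sum(il), n_total = sum(shell))
  }))
  attr(out, "r_shell") <- r_shell
  class(out) <- c("solvation_census", "data.frame")
  out
}

#' Detect the ice-binding time from a solvation census
#'
#' The binding time is the earliest time from which the ice-like shell count
#' stays at or above `k_ice` continuously for at least `dwell` ns.
#'
#' @param census a `solvation_census`.
#' @param k_ice minimum ice-like count (default 4).
#' @param dwell minimum continuous dwell, ns (default 5).
#' @return binding time in ns, or NA if the criterion is never met.
#' @export
detect_binding <- function(census, k_ice = 4, dwell = 5) {
  if (diff(range(census$time)) < dwell) {
    stop("census span is shorter than the dwell requirement", call. = FALSE)
  }
  ok <- census$n_icelike >= k_ice
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    t0 <- census$time[starts[i]]
    t1 <- census$time[ends[i]]
    if (t1 - t0 >= dwell) return(t0)
  }
  NA_real_
}

#' Dihedral torsion series
#'
#' Signed dihedral (IUPAC convention, cis = 0) of four atoms across frames,
#' with a moving-average smoothed series. Following common practice for long
#' trajectories, smoothed values are only reported where the full window
#' fits; the edges are omitted, not padded.
#'
#' @param fs a `frame_set`.
#' @param atom_quadruple four distinct atom indices (or names).
#' @param smooth_window moving-average window in points (default 5000; use a
#'   window matched to the series length for short trajectories).
#' @return a `torsion_series` data.frame: `time`, `phi` (degrees),
#'   `phi_smooth` (NA where the window does not fit).
#' @export
torsion_series <- function(fs, atom_quadruple = c("C1", "S1", "S2", "C2"),
                           smooth_window = 5000) {
  if (is.character(atom_quadruple)) {
    atom_quadruple <- vapply(atom_quadruple, function(nm) atom_idx(fs, nm)[1], 0L)
  }
  if (length(unique(atom_quadruple)) != 4 || anyNA(atom_quadruple)) {
    stop("torsion needs four distinct atoms", call. = FALSE)
  }
  phi <- vapply(seq_len(n_frames(fs)), function(k) {
    x <- fs$coords[atom_quadruple, , k]
    dihedral_angle(x[1, ], x[2, ], x[3, ], x[4, ])
  }, 0)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2 == 0) w <- w + 1L
  sm <- if (w <= length(phi)) as.numeric(stats::filter(phi, rep(1 / w, w), sides = 2))
        else rep(NA_real_, length(phi))
  out <- data.frame(time = fs$times, phi = phi, phi_smooth = sm)
  attr(out, "smooth_window") <- w
  class(out) <- c("torsion_series", "data.frame")
  out
}

#' Torsion-hydration map
#'
#' Normalized 2D histogram of (torsion angle, shell water count) over a time
#' window, mirroring contour-plot analyses of conformer-dependent hydration.
#' Total mass is 1 within the window.
#'
#' @param torsion a `torsion_series`.
#' @param census a `solvation_census` on the same time grid.
#' @param window length-2 time span in ns, or NULL for the full overlap. Use
#'   [pre_binding_window()] for the standard presets.
#' @param phi_breaks torsion bin edges, degrees.
#' @param count_type `"total"` (all shell waters) or `"liquid"`.
#' @return list: `density` matrix (torsion bins x count bins, mass 1),
#'   `phi_mid`, `counts` (the distinct count values), `window`.
#' @export
phi_hydration_map <- function(torsion, census, window = NULL,
                              phi_breaks = seq(-180, 180, by = 15),
                              count_type = c("total", "liquid")) {
  count_type <- match.arg(count_type)
  tt <- intersect(torsion$time, census$time)
  if (!is.null(window)) tt <- tt[tt >= window[1] & tt <= window[2]]
  if (!length(tt)) stop("empty time window", call. = FALSE)
  phi <- torsion$phi[match(tt, torsion$time)]
  cnt <- census[[if (count_type == "total") "n_total" else "n_liquid"]][
    match(tt, census$time)]
  keep <- !is.na(phi)
  phi <- phi[keep]; cnt <- cnt[keep]
  pb <- findInterval(phi, phi_breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cvals <- sort(unique(cnt))
  dens <- matrix(0, length(phi_breaks) - 1, length(cvals),
                 dimnames = list(NULL, cvals))
  for (i in seq_along(phi)) {
    j <- match(cnt[i], cvals)
    dens[pb[i], j] <- dens[pb[i], j] + 1
  }
  dens <- dens / sum(dens)
  list(density = dens,
       phi_mid = (phi_breaks[-1] + phi_breaks[-length(phi_breaks)]) / 2,
       counts = cvals, window = window %||% range(tt))
}

#' Standard pre-binding time windows
#'
#' @param t_bind binding time, ns.
#' @param last_ns if given, restrict to the last `last_ns` ns before binding
#'   (the "short time frame prior to binding" preset); otherwise the full
#'   pre-binding span from `t_start`.
#' @param t_start trajectory start time, ns.
#' @export
pre_binding_window <- function(t_bind, last_ns = NULL, t_start = 0) {
  if (is.null(last_ns)) c(t_start, t_bind) else c(t_bind - last_ns, t_bind)
}

#' Geometric hydrogen-bond counts
#'
#' A donor-acceptor pair is hydrogen bonded when the heavy-atom distance is
#' at most `dist_cut` and the H-donor-acceptor angle is at most `angle_cut`
#' for some hydrogen covalently attached to the donor. Counts are split by
#' the acceptor water's phase label (ice-like vs not) when labels are given.
#'
#' @param fs a `frame_set`.
#' @param donors indices of donor heavy atoms; their hydrogens are located
#'   among atoms of the same `mol_id` within 1.25 A (an error names any donor
#'   without one).
#' @param acceptors indices of acceptor atoms (typically water oxygens).
#' @param labels_list optional per-frame labels to split by acceptor phase.
#' @param frames frame indices (default all, or the labelled frames).
#' @param dist_cut heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_cut H-donor-acceptor angle cutoff, degrees (default 30).
#' @return data.frame: `time`, `donor`, `n_ice`, `n_other` (per-frame
#'   per-donor bond counts; `n_ice` is 0 when no labels are given).
#' @export
hydrogen_bonds <- function(fs, donors, acceptors, labels_list = NULL,
                           frames = NULL, dist_cut = 3.5, angle_cut = 30) {
  if (is.null(frames)) {
    frames <- if (!is.null(labels_list)) {
      attr(labels_list, "frames") %||% seq_along(labels_list)
    } else seq_len(n_frames(fs))
  }
  box <- effective_box(fs)
  widx <- if (!is.null(labels_list)) {
    attr(labels_list, "water_idx") %||% water_o_idx(fs)
  } else NULL

  ## attach hydrogens to donors from frame 1 geometry
  x1 <- fs$coords[, , frames[1], drop = TRUE]
  hyd_all <- which(fs$atoms$element == "H")
  don_h <- lapply(donors, function(d) {
    h <- integer()
    if (length(hyd_all)) {
      dd <- pair_dist(matrix(x1[d, ], 1), x1[hyd_all, , drop = FALSE], box = box)
      h <- hyd_all[dd[1, ] <= 1.25]
    }
    if (!length(h)) {
      stop(sprintf("donor atom %d (%s) has no attached hydrogens",
                   d, fs$atoms$name[d]), call. = FALSE)
    }
    h
  })

  out <- list()
  for (ii in seq_along(frames)) {
    k <- frames[ii]
    x <- fs$coords[, , k, drop = TRUE]
    ice_acc <- rep(FALSE, length(acceptors))
    if (!is.null(labels_list)) {
      pos <- match(acceptors, widx)
      lab <- labels_list[[ii]]$label[pos]
      ice_acc <- !is.na(pos) & ice_like(lab)
    }
    for (di in seq_along(donors)) {
      d <- donors[di]
      da <- pair_dist(matrix(x[d, ], 1), x[acceptors, , drop = FALSE], box = box)[1, ]
      close <- which(da <= dist_cut & acceptors != d & da > 1e-6)
      bonded <- logical(length(close))
      for (ci in seq_along(close)) {
        a <- acceptors[close[ci]]
        for (h in don_h[[di]]) {
          vh <- min_image(matrix(x[h, ] - x[d, ], 1), box)[1, ]
          va <- min_image(matrix(x[a, ] - x[d, ], 1), box)[1, ]
          ang <- acos(pmin(pmax(sum(vh * va) /
                                  sqrt(sum(vh^2) * sum(va^2)), -1), 1)) * 180 / pi
          if (ang <= angle_cut) { bonded[ci] <- TRUE; break }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        time = fs$times[k], donor = d,
        n_ice = sum(bonded & ice_acc[close]),
        n_other = sum(bonded & !ice_acc[close]))
    }
  }
  do.call(rbind, out)
}

#' Distance probability density for an atom pair
#'
#' Histogram density (integral 1) of the minimum-image distance between two
#' atoms across frames, e.g. the C-beta/C-beta distance of a Thr-Thr pair
#' before and after ice binding.
#'
#' @param fs a `frame_set`.
#' @param atom_a,atom_b atom indices.
#' @param window optional length-2 time span in ns.
#' @param bin_width histogram bin width, Angstrom (default 0.2).
#' @return a `pair_pdf` data.frame: `mid`, `density`; distances attached as
#'   an attribute.
#' @export
residue_pair_pdf <- function(fs, atom_a, atom_b, window = NULL, bin_width = 0.2) {
  keep <- rep(TRUE, n_frames(fs))
  if (!is.null(window)) keep <- fs$times >= window[1] & fs$times <= window[2]
  if (!any(keep)) stop("empty time window", call. = FALSE)
  box <- effective_box(fs)
  dx <- t(fs$coords[atom_a, , keep, drop = TRUE] -
            fs$coords[atom_b, , keep, drop = TRUE])
  if (sum(keep) == 1) dx <- matrix(dx, 1, 3)
  d <- sqrt(rowSums(min_image(dx, box)^2))
  breaks <- seq(floor(min(d) / bin_width) * bin_width,
                ceiling(max(d) / bin_width) * bin_width + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  out <- data.frame(mid = h$mids, density = h$density)
  attr(out, "distances") <- d
  attr(out, "bin_width") <- bin_width
  class(out) <- c("pair_pdf", "data.frame")
  out
}

#' RMSD series against a reference frame
#'
#' @param fs a `frame_set`.
#' @param atom_selection atom indices (default all).
#' @param reference reference frame index (default 1).
#' @param superpose optimally superpose each frame onto the reference first
#'   (default TRUE; requires >= 3 atoms).
#' @return data.frame `time`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(fs, atom_selection = seq_len(nrow(fs$atoms)),
                        reference = 1, superpose = TRUE) {
  if (superpose && length(atom_selection) < 3) {
    stop("superposed RMSD needs at least 3 atoms", call. = FALSE)
  }
  ref <- fs$coords[atom_selection, , reference, drop = TRUE]
  vals <- vapply(seq_len(n_frames(fs)), function(k) {
    rmsd(fs$coords[atom_selection, , k, drop = TRUE], ref, superpose = superpose)
  }, 0)
  data.frame(time = fs$times, rmsd = vals)
}
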