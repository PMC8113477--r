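## Synthetic systems: random liquid boxes and scripted ice-growth/binding
## trajectories with embedded ground truth.
##
## The trajectories are kinematic, not physical: the ice front advances at a
## prescribed rate, molecules overtaken by the front snap onto lattice sites,
## and a probe (a methyl carbon plus a C-S-S-C chain realizing a torsion
## schedule) approaches the front and sits in ice contact from a prescribed
## binding time onward. The analyses, not the dynamics, are the subject; the
## generator's job is exact, recoverable ground truth.

WATER_OH <- 0.9572     # O-H bond length, Angstrom
WATER_HOH <- 104.52    # H-O-H angle, degrees

## Two H positions for an O at `o`, orientation given by a random rotation.
water_hydrogens <- function(o, rot) {
  half <- WATER_HOH / 2 * pi / 180
  h1 <- c(sin(half), 0, cos(half)) * WATER_OH
  h2 <- c(-sin(half), 0, cos(half)) * WATER_OH
  rbind(o + as.numeric(rot %*% h1), o + as.numeric(rot %*% h2))
}

random_rotation <- function() {
  ## uniform random rotation via QR of a Gaussian matrix, det +1 enforced
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a random liquid water box
#'
#' Random sequential insertion of water molecules (random positions and
#' orientations) under a minimum O-O separation; the molecule count is
#' `round(density * volume)`.
#'
#' @param box orthorhombic box lengths, Angstrom.
#' @param density molecules per cubic Angstrom (default 0.0334, liquid water).
#' @param min_separation minimum O-O distance, Angstrom.
#' @param seed integer seed.
#' @param max_tries_per_mol insertion attempt budget per molecule.
#' @return a single-frame `frame_set`.
#' @export
build_liquid_box <- function(box, density = 0.0334, min_separation = 2.4,
                             seed = 1L, max_tries_per_mol = 200L) {
  box <- as.numeric(box)
  n <- round(density * prod(box))
  with_seed(seed, {
    o <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    budget <- max(1L, n) * max_tries_per_mol
    while (placed < n && tries < budget) {
      tries <- tries + 1L
      cand <- stats::runif(3) * box
      if (placed == 0L ||
          min(pair_dist(matrix(cand, 1), o[seq_len(placed), , drop = FALSE],
                        box = box)) >= min_separation) {
        placed <- placed + 1L
        o[placed, ] <- cand
      }
    }
    if (placed < n) {
      stop("could not place all molecules; lower density or min_separation",
           call. = FALSE)
    }
    coords <- matrix(NA_real_, 3 * n, 3)
    for (m in seq_len(n)) {
      coords[3 * m - 2, ] <- o[m, ]
      coords[(3 * m - 1):(3 * m), ] <- water_hydrogens(o[m, ], random_rotation())
    }
    atoms <- data.frame(
      name = rep(c("OW", "HW1", "HW2"), n),
      element = rep(c("O", "H", "H"), n),
      role = rep(c("water_O", "water_H", "water_H"), n),
      mol_id = rep(seq_len(n), each = 3),
      resid = rep(seq_len(n), each = 3),
      restype = rep("HOH", 3 * n)
    )
    frame_set(coords, atoms, box, times = 0,
              truth = list(kind = "liquid", density = density))
  })
}

#' Parameters for a scripted growth/binding trajectory
#'
#' @param n_cells lattice repeats `(nx, ny, nz)` of the 8-molecule
#'   orthorhombic ice Ih cell; the box is the full lattice extent.
#' @param lattice_params hexagonal lattice constants `a`, `c` (Angstrom).
#' @param ice_thickness0 initial ice-front position z0, Angstrom.
#' @param front_phase_jitter add a seed-dependent uniform offset in [0, c) to
#'   z0 so the front's phase relative to the lattice layers differs between
#'   seeds (default TRUE; averages out layer discreteness across replicates).
#' @param growth_rate front velocity v, Angstrom/ns (>= 0).
#' @param post_bind_factor multiplier on v after the probe binds (growth
#'   hindrance; 1 = no slowdown).
#' @param frame_interval ns between frames.
#' @param n_frames number of frames.
#' @param sigma thermal jitter on liquid molecules, Angstrom; ice molecules
#'   get sigma/3.
#' @param t_bind probe binding time, ns (NA = the probe never binds).
#' @param liquid_displacement half-width of the per-molecule uniform
#'   displacement that disorders liquid home positions, Angstrom.
#' @param approach_offset probe height above the front while diffusing in the
#'   bulk, Angstrom.
#' @param contact_distance probe height above the front once bound, Angstrom;
#'   the default 0.5 puts the methyl carbon in the plane of the topmost water
#'   layer, i.e. nestled in a surface pocket.
#' @param approach_ns duration of the final descent to contact, ns.
#' @param torsion_schedule function of time (ns) returning the scripted
#'   C-S-S-C torsion in degrees; default a two-conformer schedule that
#'   switches from -85 to +85 degrees halfway to the binding time.
#' @param seed integer seed.
#' @export
scripted_params <- function(n_cells = c(3, 2, 12),
                            lattice_params = list(a = 4.50, c = 7.34),
                            ice_thickness0 = 12,
                            front_phase_jitter = TRUE,
                            growth_rate = 0.5,
                            post_bind_factor = 0.1,
                            frame_interval = 1,
                            n_frames = 90,
                            sigma = 0.2,
                            t_bind = 60,
                            liquid_displacement = 2.2,
                            approach_offset = 18,
                            contact_distance = 0.5,
                            approach_ns = 2,
                            torsion_schedule = NULL,
                            seed = 1L) {
  stopifnot(growth_rate >= 0, sigma >= 0, n_frames >= 1, frame_interval > 0)
  if (is.null(torsion_schedule)) {
    switch_t <- if (is.finite(t_bind)) t_bind / 2 else (n_frames * frame_interval) / 2
    torsion_schedule <- function(t) ifelse(t < switch_t, -85, 85)
  }
  structure(list(
    n_cells = as.integer(n_cells), lattice_params = lattice_params,
    ice_thickness0 = ice_thickness0, front_phase_jitter = front_phase_jitter,
    growth_rate = growth_rate,
    post_bind_factor = post_bind_factor, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), sigma = sigma, t_bind = t_bind,
    liquid_displacement = liquid_displacement,
    approach_offset = approach_offset, contact_distance = contact_distance,
    approach_ns = approach_ns,
    torsion_schedule = torsion_schedule, seed = as.integer(seed)
  ), class = "scripted_params")
}

## Scripted front position at time t (ns): advances at v until t_bind, then
## at post_bind_factor * v.
scripted_front <- function(p, t) {
  tb <- if (is.finite(p$t_bind %||% NA)) p$t_bind else Inf
  p$ice_thickness0 + p$growth_rate * pmin(t, tb) +
    p$post_bind_factor * p$growth_rate * pmax(0, t - tb)
}

## C-S-S-C chain realizing dihedral phi (degrees), IUPAC sign convention,
## plus a methyl carbon bonded below the first chain atom. Row order:
## CM, C1, S1, S2, C2 (the torsion quadruple is rows 2:5).
probe_geometry <- function(phi_deg, d_cs = 1.81, d_ss = 2.05, theta = 103) {
  th <- theta * pi / 180
  phi <- phi_deg * pi / 180
  p2 <- c(0, 0, 0)
  p3 <- c(d_ss, 0, 0)
  p1 <- d_cs * c(cos(th), sin(th), 0)
  p4 <- p3 + d_cs * c(-cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
  cm <- p1 + c(0, 0, -1.8)
  rbind(CM = cm, C1 = p1, S1 = p2, S2 = p3, C2 = p4)
}

#' Generate a scripted ice-growth/binding trajectory
#'
#' Every water molecule owns one lattice site of a proton-disordered ice Ih
#' slab spanning the box. At time t, molecules whose site lies below the
#' scripted front `z0 + v * t` sit on their site (jitter sigma/3); molecules
#' above it sit at a disordered home position (site plus a fixed uniform
#' displacement, jitter sigma). A probe methyl carbon with a C-S-S-C chain
#' descends to the front, touches it at `t_bind`, and rides it afterwards;
#' the chain's torsion follows the scripted schedule exactly. The full ground
#' truth (front positions, per-frame per-molecule ice mask, binding time,
#' torsion values) is embedded in `$truth`.
#'
#' The box is periodic in x and y only; z is a slab axis.
#'
#' @param params a [scripted_params()] object.
#' @return a `frame_set` with roles `water_O`, `water_H` and `probe`.
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "scripted_params"))
  p <- params
  ice <- build_ice_ih(p$n_cells, p$lattice_params, seed = p$seed)
  box <- ice$box
  nmol <- nrow(ice$oxygen)
  times <- (seq_len(p$n_frames) - 1) * p$frame_interval

  ## per-molecule ice hydrogens from the Bernal-Fowler assignment
  hyd_of <- split(seq_len(nrow(ice$hydrogen)), ice$bonds$owner)
  site_h <- lapply(seq_len(nmol), function(m) ice$hydrogen[hyd_of[[as.character(m)]], , drop = FALSE])

  with_seed(p$seed + 1L, {
    phase <- if (isTRUE(p$front_phase_jitter)) {
      stats::runif(1, 0, p$lattice_params$c)
    } else 0
    front <- phase + scripted_front(p, times)
    if (any(front > box[3])) {
      keep <- front <= box[3]
      warning(sprintf("front reaches the box top; truncating to %d frames",
                      sum(keep)), call. = FALSE)
      times <- times[keep]
      front <- front[keep]
      p$n_frames <- length(times)
    }
    ## kinetic roughening at constant flux: molecules convert one at a time
    ## in (noisy) order of site height, with conversion thresholds on an
    ## exactly uniform z grid. Conversions within a crystal layer are thereby
    ## staggered (rough interface, random order via the tie-breaking jitter)
    ## while the converted count grows strictly linearly with front position,
    ## so the tracked front carries no layer-comb or counting noise.
    ord <- order(ice$oxygen[, 3] +
                   stats::runif(nmol, -p$lattice_params$c / 4,
                                p$lattice_params$c / 4))
    conv_z <- numeric(nmol)
    conv_z[ord] <- (seq_len(nmol) - 0.5) * box[3] / nmol

    liq_rot <- lapply(seq_len(nmol), function(m) random_rotation())

    n_water_atoms <- 3L * nmol
    n_atoms <- n_water_atoms + 5L
    coords <- array(NA_real_, c(n_atoms, 3, p$n_frames))
    ice_truth <- matrix(FALSE, nmol, p$n_frames)
    phi_truth <- p$torsion_schedule(times)
    tb <- if (is.finite(p$t_bind %||% NA)) p$t_bind else Inf

    o_rows <- seq(1, n_water_atoms, by = 3)
    for (k in seq_len(p$n_frames)) {
      is_ice <- conv_z < front[k]
      ice_truth[, k] <- is_ice
      ## liquid disorder is redrawn every frame: bulk liquid decorrelates far
      ## faster than the frame spacing, so per-frame independent
      ## configurations are the realistic limit
      disp <- matrix(stats::runif(3 * nmol, -p$liquid_displacement,
                                  p$liquid_displacement), nmol, 3)
      liq_home <- wrap_box(ice$oxygen + disp, box)
      jit <- matrix(stats::rnorm(3 * nmol), nmol, 3) *
        ifelse(is_ice, p$sigma / 3, p$sigma)
      o <- ifelse(is_ice, 1, 0) * ice$oxygen + ifelse(is_ice, 0, 1) * liq_home + jit
      fr <- matrix(NA_real_, n_water_atoms, 3)
      fr[o_rows, ] <- o
      for (m in seq_len(nmol)) {
        if (is_ice[m]) {
          fr[(3 * m - 1):(3 * m), ] <- site_h[[m]] + rep(jit[m, ], each = 2)
        } else {
          fr[(3 * m - 1):(3 * m), ] <- water_hydrogens(o[m, ], liq_rot[[m]])
        }
      }
      ## probe path: bulk diffusion height, a short final descent, then
      ## contact with the front from t_bind onward
      t <- times[k]
      height <- if (!is.finite(tb) || t <= tb - p$approach_ns) {
        p$approach_offset
      } else if (t >= tb) {
        p$contact_distance
      } else {
        p$contact_distance + (p$approach_offset - p$contact_distance) *
          (tb - t) / p$approach_ns
      }
      ## the probe binds where the converted surface is dense: the 20th
      ## highest converted site lies in the middle of the rough interface,
      ## not on an isolated protruding molecule
      top_ice <- if (any(is_ice)) {
        zi <- sort(ice$oxygen[is_ice, 3], decreasing = TRUE)
        zi[min(length(zi), 20L)]
      } else front[k]
      probe_z <- top_ice + height
      pr <- probe_geometry(phi_truth[k])
      pr <- sweep(pr, 2, c(box[1] / 2, box[2] / 2, probe_z) - pr[1, ], "+")
      coords[, , k] <- rbind(fr, pr)
    }

    atoms <- rbind(
      data.frame(name = rep(c("OW", "HW1", "HW2"), nmol),
                 element = rep(c("O", "H", "H"), nmol),
                 role = rep(c("water_O", "water_H", "water_H"), nmol),
                 mol_id = rep(seq_len(nmol), each = 3),
                 resid = rep(seq_len(nmol), each = 3),
                 restype = "HOH"),
      data.frame(name = c("CM", "C1", "S1", "S2", "C2"),
                 element = c("C", "C", "S", "S", "C"),
                 role = "probe",
                 mol_id = nmol + 1L, resid = nmol + 1L, restype = "PRB")
    )

    frame_set(coords, atoms, box, times, periodic = c(TRUE, TRUE, FALSE),
              truth = list(
                kind = "scripted_growth",
                growth_rate = p$growth_rate, t_bind = p$t_bind,
                front_phase = phase,
                post_bind_factor = p$post_bind_factor,
                front_z = front, ice_mask = ice_truth, phi = phi_truth,
                face = "primary prismatic (synthetic stand-in)",
                params = p[setdiff(names(p), "torsion_schedule")]
              ))
  })
}
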