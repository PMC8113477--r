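## End-to-end synthetic reproduction workflows: configuration handling, the
## per-trajectory analysis pipeline (classify -> front -> census -> binding ->
## torsion -> maps -> hydrogen bonds -> distance PDFs -> RMSD), and the
## mutational essentiality report.

TRAJ_CONFIG_KEYS <- c(
  "seeds", "n_cells", "lattice_a", "lattice_c", "ice_thickness0",
  "growth_rate", "post_bind_factor", "frame_interval", "n_frames", "sigma",
  "t_bind", "staggered", "eclipsed", "r_cut", "r_shell", "k_ice", "dwell",
  "smooth_window", "bin_width", "torsion_smooth_window", "out_dir"
)

#' Build a pipeline run configuration
#'
#' All tunables of the trajectory pipeline in one serializable list. Unknown
#' keys are rejected, and every run writes the resolved configuration (and
#' its hash) alongside its outputs.
#'
#' @param seeds one seed per trajectory.
#' @param n_cells lattice repeats of the 8-molecule cell.
#' @param lattice_a,lattice_c lattice constants, Angstrom.
#' @param ice_thickness0 initial front position, Angstrom.
#' @param growth_rate scripted front velocity, Angstrom/ns.
#' @param post_bind_factor growth-rate multiplier after binding.
#' @param frame_interval ns per frame.
#' @param n_frames frames per trajectory.
#' @param sigma liquid thermal jitter, Angstrom.
#' @param t_bind scripted binding time, ns.
#' @param staggered,eclipsed,r_cut phase-classification cutoffs.
#' @param r_shell solvation-shell radius, Angstrom.
#' @param k_ice,dwell binding-detection parameters.
#' @param smooth_window front smoothing window, points.
#' @param bin_width front-profile z bin width, Angstrom.
#' @param torsion_smooth_window torsion moving-average window, points.
#' @param out_dir output directory.
#' @export
trajectory_config <- function(seeds = 1:3, n_cells = c(3, 2, 12),
                        lattice_a = 4.50, lattice_c = 7.34,
                        ice_thickness0 = 12, growth_rate = 0.5,
                        post_bind_factor = 0.1, frame_interval = 1,
                        n_frames = 90, sigma = 0.2, t_bind = 60,
                        staggered = -0.8, eclipsed = c(-0.35, 0.25),
                        r_cut = 3.5, r_shell = 5.4, k_ice = 4, dwell = 5,
                        smooth_window = 11, bin_width = 1.5,
                        torsion_smooth_window = 11,
                        out_dir = tempfile("traj_run_")) {
  cfg <- list(seeds = seeds, n_cells = n_cells, lattice_a = lattice_a,
              lattice_c = lattice_c, ice_thickness0 = ice_thickness0,
              growth_rate = growth_rate, post_bind_factor = post_bind_factor,
              frame_interval = frame_interval, n_frames = n_frames,
              sigma = sigma, t_bind = t_bind, staggered = staggered,
              eclipsed = eclipsed, r_cut = r_cut, r_shell = r_shell,
              k_ice = k_ice, dwell = dwell, smooth_window = smooth_window,
              bin_width = bin_width,
              torsion_smooth_window = torsion_smooth_window,
              out_dir = out_dir)
  validate_trajectory_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and missing required keys, naming the offender.
#'
#' @param cfg a configuration list.
#' @return the validated configuration, invisibly classed `trajectory_config`.
#' @export
validate_trajectory_config <- function(cfg) {
  unknown <- setdiff(names(cfg), TRAJ_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(TRAJ_CONFIG_KEYS, names(cfg))
  if (length(missing)) {
    stop("missing configuration key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "trajectory_config")
}

## md5 of the JSON-serialized configuration, for output provenance; the
## output directory is excluded so the hash identifies the analysis
## parameters, not where results land
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the trajectory analysis pipeline
#'
#' Generates one scripted trajectory per seed and runs the full analysis
#' stack: phase classification, front tracking and growth rate, solvation
#' census and binding detection, torsion series and torsion-hydration map,
#' shell-water hydrogen bonds to ice, a probe atom-pair distance PDF, and the
#' probe RMSD series. Per-trajectory CSV/JSON reports and an aggregate report
#' are written under `cfg$out_dir`; every artifact carries the configuration
#' hash. A failure in one trajectory is recorded and the run continues.
#'
#' @param cfg a [trajectory_config()] (or compatible list, which is validated).
#' @return invisibly, a list with per-trajectory results and the aggregate.
#' @export
run_trajectory_pipeline <- function(cfg) {
  if (!inherits(cfg, "trajectory_config")) cfg <- validate_trajectory_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  jsonlite::write_json(c(unclass(cfg), list(config_hash = hash)),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cutoffs <- phase_cutoffs(cfg$staggered, cfg$eclipsed, cfg$r_cut)
  results <- list()
  failures <- character()

  for (seed in cfg$seeds) {
    tag <- sprintf("traj_%03d", seed)
    res <- tryCatch({
      p <- scripted_params(
        n_cells = cfg$n_cells,
        lattice_params = list(a = cfg$lattice_a, c = cfg$lattice_c),
        ice_thickness0 = cfg$ice_thickness0, growth_rate = cfg$growth_rate,
        post_bind_factor = cfg$post_bind_factor,
        frame_interval = cfg$frame_interval, n_frames = cfg$n_frames,
        sigma = cfg$sigma, t_bind = cfg$t_bind, seed = seed)
      fs <- generate_trajectory(p)
      labs <- classify_frameset(fs, cutoffs = cutoffs)
      fr <- front_series(fs, labs, bin_width = cfg$bin_width)
      gr <- growth_rate(fr, smooth_window = cfg$smooth_window)
      cen <- solvation_census(fs, labs, r_shell = cfg$r_shell)
      t_detect <- detect_binding(cen, k_ice = cfg$k_ice, dwell = cfg$dwell)
      tor <- torsion_series(fs, smooth_window = cfg$torsion_smooth_window)
      pre_w <- pre_binding_window(if (is.na(t_detect)) max(fs$times) else t_detect)
      map <- phi_hydration_map(tor, cen, window = pre_w)
      frc <- front_series(fs, labs, method = "count")
      rate_pre <- mean_growth_rate(frc, c(min(fs$times) + 2,
                                          (if (is.na(t_detect)) max(fs$times)
                                           else t_detect) - 2))
      ## hydrogen bonds from probe-shell waters to ice-labelled waters,
      ## final frame
      kf <- n_frames(fs)
      widx <- water_o_idx(fs)
      cm <- atom_idx(fs, "CM")[1]
      dshell <- pair_dist(fs$coords[widx, , kf], matrix(fs$coords[cm, , kf], 1),
                          box = effective_box(fs))[, 1]
      shell_don <- widx[dshell <= cfg$r_shell]
      labs_last <- labs[length(labs)]
      attr(labs_last, "water_idx") <- widx
      attr(labs_last, "frames") <- kf
      hb <- if (length(shell_don)) {
        hydrogen_bonds(fs, donors = shell_don, acceptors = widx,
                       labels_list = labs_last, frames = kf)
      } else NULL
      pdf_cm <- residue_pair_pdf(fs, atom_idx(fs, "CM")[1], atom_idx(fs, "C2")[1])
      rms <- rmsd_series(fs, atom_selection = which(fs$atoms$role == "probe"))

      utils::write.csv(cbind(fr, config_hash = hash),
                       file.path(cfg$out_dir, paste0(tag, "_front.csv")),
                       row.names = FALSE)
      utils::write.csv(cbind(cen, config_hash = hash),
                       file.path(cfg$out_dir, paste0(tag, "_census.csv")),
                       row.names = FALSE)
      utils::write.csv(cbind(tor, config_hash = hash),
                       file.path(cfg$out_dir, paste0(tag, "_torsion.csv")),
                       row.names = FALSE)
      report <- list(
        seed = seed, config_hash = hash,
        binding_time_ns = t_detect,
        truth_t_bind_ns = fs$truth$t_bind,
        recovered_rate_pre = rate_pre,
        truth_rate = fs$truth$growth_rate,
        mean_shell_liquid = mean(cen$n_liquid),
        hbonds_to_ice_final = if (is.null(hb)) NA else sum(hb$n_ice),
        mean_probe_rmsd = mean(rms$rmsd)
      )
      jsonlite::write_json(report, file.path(cfg$out_dir, paste0(tag, "_report.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(report, list(front = fr, rate = gr, census = cen, torsion = tor,
                     map = map, pdf = pdf_cm, rmsd = rms))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", tag, conditionMessage(e)))
      NULL
    })
    results[[tag]] <- res
  }

  ok <- !vapply(results, is.null, TRUE)
  agg <- list(
    config_hash = hash,
    n_trajectories = length(cfg$seeds),
    n_failed = sum(!ok),
    failures = failures,
    mean_recovered_rate = mean(vapply(results[ok], `[[`, 0, "recovered_rate_pre")),
    scripted_rate = cfg$growth_rate,
    binding_times = vapply(results[ok], `[[`, 0, "binding_time_ns"),
    scripted_t_bind = cfg$t_bind
  )
  jsonlite::write_json(agg, file.path(cfg$out_dir, "aggregate_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trajectories = results, aggregate = agg, out_dir = cfg$out_dir))
}

#' Run the mutational essentiality report
#'
#' Evaluates the mutational-activity table (the packaged fixture by default):
#' per-variant activity calls, the essential-residue set at the headline
#' concentration, and the canonical scaffold record.
#'
#' @param activity_csv path to an activity CSV; NULL for the packaged fixture.
#' @param concentration headline concentration, mg/mL.
#' @param activity_threshold ratio cutoff for the activity call.
#' @param out_dir output directory, or NULL to skip writing.
#' @return list: `essential` (positions), `table`, `scaffold_record`,
#'   `threshold`.
#' @export
run_mutational_report <- function(activity_csv = NULL, concentration = 1,
                                  activity_threshold = 0.8, out_dir = NULL) {
  tab <- if (is.null(activity_csv)) {
    packaged_activity_table(activity_threshold = activity_threshold)
  } else {
    read_activity_table(activity_csv, activity_threshold = activity_threshold)
  }
  ess <- essential_residues(tab, concentration)
  sc <- build_canonical_scaffold()
  out <- list(essential = ess,
              table = as.data.frame(tab),
              scaffold_record = scaffold_to_record(sc),
              threshold = activity_threshold,
              concentration = concentration)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(out_dir, "mutational_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
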