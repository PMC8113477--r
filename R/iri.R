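## Ice recrystallization inhibition quantification from grain label maps:
## per-grain areas, mean grain area, sample/control ratios, dose-response
## summaries; plus a Voronoi grain-map generator with known mean grain area.

#' Generate a Voronoi grain label map
#'
#' Tessellates a `width` x `height` pixel image into `n_grains` Voronoi cells
#' around uniformly random seed points; every pixel is labelled 1..n_grains
#' (nearest seed, ties to the lower label).
#'
#' @param width,height image size in pixels.
#' @param n_grains number of grains (>= 1).
#' @param seed integer seed.
#' @return integer matrix (`height` rows x `width` columns) of class
#'   `grain_map`, with the seed points attached as attribute `seeds`.
#' @export
generate_grain_map <- function(width, height, n_grains, seed = 1L) {
  stopifnot(n_grains >= 1, width >= 1, height >= 1)
  with_seed(seed, {
    sx <- stats::runif(n_grains, 0.5, width + 0.5)
    sy <- stats::runif(n_grains, 0.5, height + 0.5)
    px <- rep(seq_len(width), each = height)
    py <- rep(seq_len(height), times = width)
    best <- rep(1L, width * height)
    bestd <- (px - sx[1])^2 + (py - sy[1])^2
    for (g in seq_len(n_grains)[-1]) {
      d <- (px - sx[g])^2 + (py - sy[g])^2
      upd <- d < bestd
      best[upd] <- g
      bestd[upd] <- d[upd]
    }
    m <- matrix(best, nrow = height, ncol = width)
    structure(m, class = c("grain_map", "matrix"),
              seeds = cbind(x = sx, y = sy))
  })
}

#' Per-grain areas and mean grain area
#'
#' Counts pixels per label (label 0 is background and ignored). With
#' `exclude_border`, grains touching the image border are dropped, since
#' partial grains bias the mean area downward.
#'
#' @param label_map integer matrix of grain labels (0 = background).
#' @param exclude_border drop border-touching grains (default TRUE).
#' @param scale area scale factor (e.g. square micrometres per pixel);
#'   default 1 reports pixel counts.
#' @return a `grain_stats` list: `areas` (named per-grain), `mean_area`,
#'   `n_grains`, `exclude_border`.
#' @export
grain_areas <- function(label_map, exclude_border = TRUE, scale = 1) {
  m <- unclass(label_map)
  if (length(m) == 0) stop("empty label map", call. = FALSE)
  labs <- m[m != 0]
  if (length(labs) == 0) stop("label map is all background", call. = FALSE)
  counts <- table(labs)
  if (exclude_border) {
    border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    counts <- counts[!(names(counts) %in% as.character(border))]
    if (length(counts) == 0) {
      message("all grains touch the border; no interior grains remain")
      return(structure(list(areas = numeric(0), mean_area = NA_real_,
                            n_grains = 0L, exclude_border = TRUE),
                       class = "grain_stats"))
    }
  }
  areas <- as.numeric(counts) * scale
  names(areas) <- names(counts)
  structure(list(areas = areas, mean_area = mean(areas),
                 n_grains = length(areas), exclude_border = exclude_border),
            class = "grain_stats")
}

#' @export
print.grain_stats <- function(x, ...) {
  cat(sprintf("<grain_stats> %d grains, mean area %.1f%s\n", x$n_grains,
              x$mean_area, if (x$exclude_border) " (border excluded)" else ""))
  invisible(x)
}

#' Mean-grain-area ratio of sample to control
#'
#' The IRI statistic: the ratio of the replicate-mean grain areas of a sample
#' to a buffer control. With matched replicates the SD of the per-replicate
#' ratios is also reported.
#'
#' @param sample,control lists of `grain_stats` (replicates), or numeric
#'   vectors of per-replicate mean grain areas.
#' @return list: `ratio`, `sd` (NA with a single replicate or unmatched
#'   replicate counts), `n_sample`, `n_control`.
#' @export
mga_ratio <- function(sample, control) {
  mga <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(g) {
      if (inherits(g, "grain_stats")) g$mean_area else as.numeric(g)
    }, 0)
  }
  s <- mga(sample); ctl <- mga(control)
  if (!length(s) || !length(ctl)) stop("need at least one replicate each", call. = FALSE)
  if (mean(ctl) == 0) stop("control mean grain area is zero", call. = FALSE)
  ratio <- mean(s) / mean(ctl)
  sd_r <- if (length(s) == length(ctl) && length(s) > 1) {
    stats::sd(s / ctl)
  } else NA_real_
  list(ratio = ratio, sd = sd_r, n_sample = length(s), n_control = length(ctl))
}

#' Dose-response summary of IRI activity
#'
#' @param table data.frame with columns `concentration` (mg/mL, positive,
#'   unique), `ratio` (mean-grain-area ratio) and optionally `sd`.
#' @param activity_threshold ratio below which a sample is called active.
#' @param headline_concentration concentration whose call is reported as the
#'   headline (default 1 mg/mL).
#' @return list: `table` (sorted, with `active` flags), `headline` (the call
#'   at the headline concentration, NA if absent), `activity_threshold`.
#' @export
dose_response <- function(table, activity_threshold = 0.8,
                          headline_concentration = 1) {
  stopifnot(all(c("concentration", "ratio") %in% names(table)))
  if (any(table$concentration <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (anyDuplicated(table$concentration)) stop("duplicate concentrations", call. = FALSE)
  tab <- table[order(table$concentration), , drop = FALSE]
  tab$active <- tab$ratio < activity_threshold
  rownames(tab) <- NULL
  hl <- tab$active[tab$concentration == headline_concentration]
  list(table = tab,
       headline = if (length(hl)) hl else NA,
       activity_threshold = activity_threshold)
}
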