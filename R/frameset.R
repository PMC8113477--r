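## Multi-frame coordinate container shared by the generators and analyses.

#' Construct a frame set
#'
#' A `frame_set` holds a multi-frame trajectory: an atoms table (one row per
#' atom: `name`, `element`, `role`, `mol_id`, `resid`, `restype`), a
#' coordinate array `n_atoms x 3 x n_frames` in Angstrom, orthorhombic box
#' lengths, per-frame time stamps in ns, periodicity flags per axis, and
#' optional ground-truth metadata attached by the generators.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single-frame matrix
#'   is promoted).
#' @param atoms data.frame with at least columns `name` and `role` (roles:
#'   `"water_O"`, `"water_H"`, `"probe"`, `"peptide"`).
#' @param box orthorhombic box lengths, Angstrom.
#' @param times per-frame time stamps, ns (strictly increasing).
#' @param periodic logical triple; FALSE switches off minimum imaging on that
#'   axis (slab geometries).
#' @param truth optional list of generator ground truth.
#' @export
frame_set <- function(coords, atoms, box, times = 0,
                      periodic = c(TRUE, TRUE, TRUE), truth = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms)) stop("coords/atoms row mismatch", call. = FALSE)
  if (dim(coords)[3] != length(times)) stop("coords/times frame mismatch", call. = FALSE)
  if (any(diff(times) <= 0) && length(times) > 1) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  structure(list(coords = coords, atoms = atoms, box = as.numeric(box),
                 times = as.numeric(times), periodic = periodic, truth = truth),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d atoms x %d frames, box %.1f x %.1f x %.1f A, t = %.3g..%.3g ns\n",
              dim(x$coords)[1], dim(x$coords)[3], x$box[1], x$box[2], x$box[3],
              min(x$times), max(x$times)))
  print(table(x$atoms$role))
  invisible(x)
}

#' Number of frames in a frame set
#' @param fs a `frame_set`.
#' @export
n_frames <- function(fs) dim(fs$coords)[3]

#' Coordinates of one frame
#' @param fs a `frame_set`.
#' @param k frame index (1-based).
#' @export
frame_coords <- function(fs, k) fs$coords[, , k, drop = TRUE]

#' Water-oxygen atom indices
#' @param fs a `frame_set`.
#' @export
water_o_idx <- function(fs) which(fs$atoms$role == "water_O")

#' Effective box for minimum imaging
#'
#' Non-periodic axes are mapped to an infinite length so minimum imaging
#' becomes a no-op there.
#' @param fs a `frame_set`.
#' @export
effective_box <- function(fs) ifelse(fs$periodic, fs$box, Inf)

#' Atom indices by atom name (optionally within a role)
#' @param fs a `frame_set`.
#' @param names atom names to look up.
#' @param role optional role filter.
#' @export
atom_idx <- function(fs, names, role = NULL) {
  sel <- fs$atoms$name %in% names
  if (!is.null(role)) sel <- sel & fs$atoms$role %in% role
  which(sel)
}
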