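#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. All boxes are orthorhombic and all
## distances use the minimum-image convention.

#' Minimum-image displacement vectors
#'
#' @param dx numeric matrix (n x 3) of raw displacement components.
#' @param box numeric length-3 orthorhombic box lengths (Angstrom).
#' @return matrix of wrapped displacements, each component in (-L/2, L/2].
#' @keywords internal
min_image <- function(dx, box) {
  dx <- as.matrix(dx)
  for (k in 1:3) {
    if (is.finite(box[k])) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  }
  dx
}

#' Pairwise minimum-image distance matrix
#'
#' @param x,y coordinate matrices (rows = points, 3 columns). `y` defaults to `x`.
#' @param box orthorhombic box lengths; NULL for open boundaries.
#' @return distance matrix nrow(x) x nrow(y).
#' @keywords internal
pair_dist <- function(x, y = x, box = NULL) {
  d2 <- matrix(0, nrow(x), nrow(y))
  for (k in 1:3) {
    dk <- outer(x[, k], y[, k], "-")
    if (!is.null(box) && is.finite(box[k])) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Wrap coordinates into the primary box [0, L)
#' @keywords internal
wrap_box <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] %% box[k]
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

## Run an expression under a local RNG seed without touching global state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Unit-normalize rows of a matrix
#' @keywords internal
row_normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("zero-length bond vector", call. = FALSE)
  m / n
}
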