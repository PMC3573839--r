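#' Image grid geometry
#'
#' Describes the voxel lattice on which all masks, distance images and
#' deviation images live. Coordinates are physical millimetres throughout;
#' voxel index `(0, 0, 0)` maps to `origin`, which is the *centre* of that
#' voxel (not its corner). The third axis always indexes slices.
#'
#' @param origin numeric(3), mm coordinate of the centre of voxel (0,0,0).
#' @param spacing numeric(3), per-axis voxel size in mm (dx, dy, dz); the
#'   slice spacing dz may differ from the in-plane spacing (anisotropic MR).
#' @param shape integer(3), voxel counts per axis (nx, ny, nz).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(origin = c(0, 0, 0), spacing = c(0.625, 0.625, 3.9),
#'                 shape = c(256, 256, 20))
#' @export
image_grid <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L)
    stop_config("grid origin, spacing and shape must each have 3 entries")
  if (any(!is.finite(origin)))
    stop_config("grid origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_config("grid spacing entries must all be > 0")
  if (any(is.na(shape)) || any(shape < 1L))
    stop_config("grid shape entries must all be >= 1")
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 slice_axis = 3L),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d x %d, spacing %g x %g x %g mm, origin (%g, %g, %g)>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# voxel-centre coordinates along one axis, mm
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# physical diagonal of the whole lattice; used to cap distances
grid_diagonal <- function(grid) {
  sqrt(sum((grid$shape * grid$spacing)^2))
}

# in-plane voxel diagonal, the raster agreement tolerance used throughout
inplane_diagonal <- function(grid) {
  sqrt(grid$spacing[1]^2 + grid$spacing[2]^2)
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(a$shape == b$shape)
}

check_same_grid <- function(a, b, what = "images") {
  if (!grids_equal(a, b))
    stop_geometry(sprintf("%s are defined on different grids", what))
  invisible(TRUE)
}

#' Refine the in-plane resolution of a grid
#'
#' Subdivides each voxel into `factor` x `factor` in-plane subvoxels while
#' keeping the physical extent covered by the lattice identical. Distance
#' and deviation images computed on the refined grid are more accurate at
#' the cost of `factor^2` more voxels per slice; slice positions are
#' unchanged.
#'
#' @param grid an [image_grid()].
#' @param factor integer >= 1, in-plane subdivision factor.
#' @return A new `image_grid`.
#' @export
refine_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop_config("refinement factor must be an integer >= 1")
  if (factor == 1L) return(grid)
  dx <- grid$spacing[1] / factor
  dy <- grid$spacing[2] / factor
  image_grid(
    origin = c(grid$origin[1] - grid$spacing[1] / 2 + dx / 2,
               grid$origin[2] - grid$spacing[2] / 2 + dy / 2,
               grid$origin[3]),
    spacing = c(dx, dy, grid$spacing[3]),
    shape = c(grid$shape[1] * factor, grid$shape[2] * factor, grid$shape[3]))
}

# condition helpers: one class per CLI failure family
stop_parse <- function(msg) {
  stop(structure(class = c("cdv_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_geometry <- function(msg) {
  stop(structure(class = c("cdv_geometry_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_config <- function(msg) {
  stop(structure(class = c("cdv_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# evaluate expr with a private RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
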