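#' Per-angle maximal deviation profile of one slice
#'
#' Collapses a slice's deviation map into a polar profile around a contour
#' centre: for each angle bin a ray is cast from the centre to the grid
#' edge, the deviation image is sampled along it (bilinear interpolation)
#' at radial steps of half the minimum in-plane spacing, and the maximum
#' over samples falling inside the disagreement region is kept. Bins whose
#' ray never meets the disagreement region are *missing* (`NA`), which is
#' distinct from a measured perfect agreement of 0 mm.
#'
#' Angle convention (image view): 0 degrees points to the image top
#' (anterior, the -y direction), -90 to the image right, +90 to the image
#' left, and +/-180 posterior; bin centres span (-180, 180].
#'
#' @param dd a `deviation_image`.
#' @param delta_i the disagreement-region `binary_mask` (sampled
#'   nearest-neighbour — interpolating a binary mask would invent
#'   fractional membership).
#' @param slice 0-based slice index.
#' @param center in-plane point `c(x, y)` in mm; must lie within the grid
#'   extent. The centre choice strongly influences angular results and is
#'   therefore recorded in the returned object.
#' @param step angular bin width in degrees; must divide 360.
#' @return An object of class `angular_profile` with `angles` (bin centres,
#'   degrees), `values` (mm or `NA`), `slice_index`, `center`, `step`.
#' @export
angular_profile <- function(dd, delta_i, slice, center, step = 1) {
  check_same_grid(dd$grid, delta_i$grid, "deviation image and disagreement mask")
  g <- dd$grid
  nbin <- 360 / step
  if (abs(nbin - round(nbin)) > 1e-9)
    stop_config("angular step must divide 360 degrees")
  nbin <- as.integer(round(nbin))
  slice <- as.integer(slice)
  if (slice < 0L || slice >= g$shape[3])
    stop_geometry(sprintf("slice %d outside grid (nz = %d)", slice, g$shape[3]))
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2)
  half <- g$spacing[1:2] / 2
  if (center[1] < xs[1] - half[1] || center[1] > xs[length(xs)] + half[1] ||
      center[2] < ys[1] - half[2] || center[2] > ys[length(ys)] + half[2])
    stop_geometry(sprintf("center (%g, %g) lies outside the grid extent",
                          center[1], center[2]))
  angles <- seq(-180 + step, 180, by = step)

  prof <- rep(NA_real_, nbin)
  if (slice %in% dd$valid_slices) {
    dm <- delta_i$values[, , slice + 1L]
    dim(dm) <- g$shape[1:2]
    # the sampled field is DD * indicator(disagreement region): values
    # outside the region are zeroed before interpolation so they can never
    # influence a profile, at the cost of a slight downward blend at the
    # region edge (bounded by the raster tolerance)
    ddm <- dd$values[, , slice + 1L] * dm
    dim(ddm) <- g$shape[1:2]
    dr <- min(g$spacing[1:2]) / 2
    rmax <- sqrt(sum((g$shape[1:2] * g$spacing[1:2])^2))
    radii <- seq(dr, rmax, by = dr)
    rad <- angles * pi / 180
    ux <- -sin(rad); uy <- -cos(rad)        # 0 deg = -y (image top/anterior)
    px <- outer(ux, radii) + center[1]      # nbin x nr
    py <- outer(uy, radii) + center[2]
    fx <- (px - g$origin[1]) / g$spacing[1] # 0-based fractional indices
    fy <- (py - g$origin[2]) / g$spacing[2]
    ingrid <- fx >= 0 & fx <= g$shape[1] - 1 & fy >= 0 & fy <= g$shape[2] - 1
    # nearest-neighbour membership in the disagreement region
    ni <- pmin(pmax(round(fx), 0), g$shape[1] - 1) + 1
    nj <- pmin(pmax(round(fy), 0), g$shape[2] - 1) + 1
    member <- ingrid & dm[cbind(as.vector(ni), as.vector(nj))]
    # bilinear deviation values
    i0 <- pmin(pmax(floor(fx), 0), g$shape[1] - 2)
    j0 <- pmin(pmax(floor(fy), 0), g$shape[2] - 2)
    wx <- fx - i0; wy <- fy - j0
    v <- (1 - wx) * (1 - wy) * ddm[cbind(as.vector(i0) + 1, as.vector(j0) + 1)] +
         wx       * (1 - wy) * ddm[cbind(as.vector(i0) + 2, as.vector(j0) + 1)] +
         (1 - wx) * wy       * ddm[cbind(as.vector(i0) + 1, as.vector(j0) + 2)] +
         wx       * wy       * ddm[cbind(as.vector(i0) + 2, as.vector(j0) + 2)]
    v[!member] <- NA_real_
    dim(v) <- dim(px)
    any_member <- rowSums(member, na.rm = TRUE) > 0
    dim(member) <- dim(px)
    prof[any_member] <- apply(v[any_member, , drop = FALSE], 1, max,
                              na.rm = TRUE)
  }
  structure(list(slice_index = slice, center = as.numeric(center[1:2]),
                 step = step, angles = angles, values = prof, grid = g),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  nm <- sum(!is.na(x$values))
  cat(sprintf("<angular_profile slice %d, center (%.2f, %.2f) mm, step %g deg: %d/%d bins measured>\n",
              x$slice_index, x$center[1], x$center[2], x$step, nm,
              length(x$values)))
  invisible(x)
}

#' Centre of gravity of a mask slice
#'
#' Mean of the set-voxel centre coordinates on one slice, in mm: the default
#' contour centre for angular analysis when no anatomical landmark (e.g.
#' an applicator axis) is supplied.
#'
#' @param mask a `binary_mask`.
#' @param slice 0-based slice index with at least one set voxel.
#' @return In-plane point `c(x, y)` in mm.
#' @export
centroid_center <- function(mask, slice) {
  g <- mask$grid
  slice <- as.integer(slice)
  if (slice < 0L || slice >= g$shape[3])
    stop_geometry(sprintf("slice %d outside grid (nz = %d)", slice, g$shape[3]))
  m <- mask$values[, , slice + 1L]
  dim(m) <- g$shape[1:2]
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop_geometry(sprintf("mask slice %d is empty; no centroid", slice))
  c(g$origin[1] + mean(idx[, 1] - 1) * g$spacing[1],
    g$origin[2] + mean(idx[, 2] - 1) * g$spacing[2])
}

#' Assemble per-slice profiles into a slice-by-angle matrix
#'
#' Each slice contributes one row, ordered by slice index over the whole
#' grid; slices without a profile (uncontoured) appear as all-missing rows,
#' so the rendered graph stays empty there.
#'
#' @param profiles list of [angular_profile()]s sharing the same binning.
#' @return A numeric matrix (rows = slices 0..nz-1, columns = angle bins)
#'   with the bin centres as column names, slice indices as row names, the
#'   common `step` as attribute `"step"` and the per-slice centres as
#'   attribute `"centers"`.
#' @export
assemble_matrix <- function(profiles) {
  if (inherits(profiles, "angular_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L)
    stop_config("assemble_matrix needs at least one profile")
  a1 <- profiles[[1]]$angles
  for (p in profiles[-1])
    if (length(p$angles) != length(a1) || any(p$angles != a1))
      stop_config("profiles have inconsistent angular binning")
  nz <- profiles[[1]]$grid$shape[3]
  mat <- matrix(NA_real_, nrow = nz, ncol = length(a1),
                dimnames = list(as.character(seq_len(nz) - 1L),
                                as.character(a1)))
  centers <- matrix(NA_real_, nrow = nz, ncol = 2)
  for (p in profiles) {
    mat[p$slice_index + 1L, ] <- p$values
    centers[p$slice_index + 1L, ] <- p$center
  }
  attr(mat, "step") <- profiles[[1]]$step
  attr(mat, "centers") <- centers
  mat
}

#' Write a slice-by-angle matrix as CSV
#'
#' One row per slice; first column is the 0-based slice index, remaining
#' columns the angle-bin centres in degrees; missing bins are `NA`.
#'
#' @param mat matrix from [assemble_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_angular_csv <- function(mat, path) {
  df <- data.frame(slice = as.integer(rownames(mat)), mat,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}
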