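new_deviation_image <- function(values, grid, mode, kind, n_analysed,
                                valid_slices) {
  structure(list(values = values, grid = grid, mode = mode, kind = kind,
                 n_analysed = as.integer(n_analysed),
                 valid_slices = as.integer(valid_slices)),
            class = "deviation_image")
}

#' @export
print.deviation_image <- function(x, ...) {
  mx <- suppressWarnings(max(x$values, na.rm = TRUE))
  cat(sprintf("<deviation_image (%s, N = %d, %s): max %.2f mm, %d valid slice(s)>\n",
              x$kind, x$n_analysed, x$mode, mx, length(x$valid_slices)))
  invisible(x)
}

check_dist_pairable <- function(a, b) {
  check_same_grid(a$grid, b$grid, "distance images")
  if (!identical(a$mode, b$mode))
    stop_config("distance images mix slice2d and volume3d modes")
}

mask_invalid_slices <- function(vals, grid, valid) {
  blank <- setdiff(seq_len(grid$shape[3]) - 1L, valid)
  if (length(blank)) vals[, , blank + 1L] <- NA_real_
  vals
}

#' Distance deviation between two contours
#'
#' The pairwise distance deviation observed from every voxel: the absolute
#' difference of the two signed distance images, `DD(x) = |D1(x) - D2(x)|`,
#' in mm. It is exactly symmetric in its arguments, detects any difference
#' between the contours regardless of shape complexity, and its maximum over
#' the disagreement region equals the Hausdorff distance of the two contours.
#'
#' @param d1,d2 `distance_image`s on the same grid and mode.
#' @return A `deviation_image` of kind `"pair"`. Valid slices are those
#'   contoured in both inputs; others are `NA`.
#' @export
dd_pair <- function(d1, d2) {
  check_dist_pairable(d1, d2)
  valid <- intersect(d1$valid_slices, d2$valid_slices)
  vals <- mask_invalid_slices(abs(d1$values - d2$values), d1$grid, valid)
  new_deviation_image(vals, d1$grid, d1$mode, "pair", 1L, valid)
}

#' Distance deviation of analysed contours against a reference
#'
#' Per-voxel RMS of the distance deviations of N analysed contours with
#' respect to a reference: `DD_R(x) = sqrt(mean_i (D_i(x) - D_R(x))^2)`.
#' The mean divides by N (population form); set `sample = TRUE` for the
#' N - 1 variant. With a single analysed contour this reduces exactly to
#' [dd_pair()].
#'
#' @param analysed list of `distance_image`s (or a single one).
#' @param reference the reference `distance_image`.
#' @param sample logical; divide squared deviations by N - 1 instead of N.
#' @return A `deviation_image` of kind `"vs_reference"` (`"pair"` when N = 1).
#' @export
dd_vs_reference <- function(analysed, reference, sample = FALSE) {
  if (inherits(analysed, "distance_image")) analysed <- list(analysed)
  n <- length(analysed)
  if (n < 1L) stop_config("dd_vs_reference needs at least one analysed image")
  for (d in analysed) check_dist_pairable(d, reference)
  if (n == 1L && !sample) return(dd_pair(analysed[[1]], reference))
  valid <- Reduce(intersect, c(lapply(analysed, `[[`, "valid_slices"),
                               list(reference$valid_slices)))
  denom <- if (sample) { if (n < 2L) stop_config(
    "sample = TRUE needs at least two analysed images") else n - 1L } else n
  ss <- Reduce(`+`, lapply(analysed,
                           function(d) (d$values - reference$values)^2))
  vals <- mask_invalid_slices(sqrt(ss / denom), reference$grid, valid)
  new_deviation_image(vals, reference$grid, reference$mode, "vs_reference",
                      n, valid)
}

#' Distance deviation without a reference
#'
#' When no ground truth exists, contouring variation is measured as the
#' per-voxel standard deviation of the distances to all analysed contours,
#' taken around the mean distance image:
#' `DD_S(x) = sqrt(mean_i (D_i(x) - Dbar(x))^2)` with
#' `Dbar = mean_i D_i` (see [mean_distance_image()]). Population form
#' (divide by N) by default, matching the defining formula; `sample = TRUE`
#' divides by N - 1.
#'
#' @param analysed list of at least two `distance_image`s.
#' @param sample logical; use the N - 1 denominator.
#' @return A `deviation_image` of kind `"std"`.
#' @export
dd_std <- function(analysed, sample = FALSE) {
  if (inherits(analysed, "distance_image")) analysed <- list(analysed)
  n <- length(analysed)
  if (n < 2L)
    stop_config("dd_std needs at least two analysed images (std of one is degenerate)")
  dbar <- mean_distance_image(analysed)
  valid <- dbar$valid_slices
  denom <- if (sample) n - 1L else n
  ss <- Reduce(`+`, lapply(analysed, function(d) (d$values - dbar$values)^2))
  vals <- mask_invalid_slices(sqrt(ss / denom), dbar$grid, valid)
  new_deviation_image(vals, dbar$grid, dbar$mode, "std", n, valid)
}

check_masks <- function(masks, min_m) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  if (length(masks) < min_m)
    stop_config(sprintf("need at least %d masks", min_m))
  g <- masks[[1]]$grid
  for (m in masks[-1]) check_same_grid(g, m$grid, "masks")
  masks
}

#' Region of contour disagreement
#'
#' The voxels covered by at least one but not all of the M delineations
#' (reference included when present). All contour differences surface in
#' this region: deviations outside the union of contours, or inside their
#' common intersection, can never exceed the maximum reached here, which is
#' why the maximal distance deviation is searched over it.
#'
#' @param masks list of M >= 2 `binary_mask`s on one grid.
#' @return A `binary_mask`; its `contoured_slices` are the slices contoured
#'   by every input (the domain on which comparison is defined).
#' @export
disagreement_region <- function(masks) {
  masks <- check_masks(masks, 2L)
  s <- Reduce(`+`, lapply(masks, function(m) m$values + 0L))
  vals <- s > 0L & s < length(masks)
  structure(list(values = vals, grid = masks[[1]]$grid,
                 contoured_slices = Reduce(intersect,
                   lapply(masks, `[[`, "contoured_slices"))),
            class = "binary_mask")
}

#' Union of delineated regions
#'
#' Voxelwise OR of the M delineation masks: the averaging domain for the
#' mean distance deviation, balancing regions of high disagreement against
#' parts where the contours agree well.
#'
#' @param masks list of M >= 1 `binary_mask`s on one grid.
#' @return A `binary_mask` (its `contoured_slices` are the intersection of
#'   the inputs', the domain on which comparison statistics are defined).
#' @export
union_region <- function(masks) {
  masks <- check_masks(masks, 1L)
  vals <- Reduce(`|`, lapply(masks, `[[`, "values"))
  structure(list(values = vals, grid = masks[[1]]$grid,
                 contoured_slices = Reduce(intersect,
                   lapply(masks, `[[`, "contoured_slices"))),
            class = "binary_mask")
}

#' Scalar summaries of a deviation image
#'
#' Collapses a deviation image into the two overall estimates: the maximal
#' distance deviation, searched over the region of contour disagreement
#' (for two contours this equals their Hausdorff distance), and the mean
#' distance deviation, averaged over the union of all delineated regions.
#' Both statistics are restricted to the deviation image's valid slices
#' (those contoured by every compared structure). An empty disagreement
#' region means perfect agreement: `dd_max = 0`. An empty union region is
#' an error.
#'
#' @param dd a `deviation_image`.
#' @param masks list of the M delineation masks that entered the comparison
#'   (reference included when present), on the same grid.
#' @param name optional structure/set label carried into reports.
#' @return An object of class `dd_summary` with fields `dd_max_mm`,
#'   `dd_mean_mm`, `n_voxels_union`, `n_voxels_disagreement`, `kind`,
#'   `n_analysed`, `m`, `name`.
#' @export
summarize_deviation <- function(dd, masks, name = NULL) {
  masks <- check_masks(masks, 2L)
  check_same_grid(dd$grid, masks[[1]]$grid, "deviation image and masks")
  delta <- disagreement_region(masks)
  uni <- union_region(masks)
  keep <- array(FALSE, dim = dd$grid$shape)
  if (length(dd$valid_slices)) keep[, , dd$valid_slices + 1L] <- TRUE
  sel_delta <- delta$values & keep
  sel_uni <- uni$values & keep
  if (!any(sel_uni))
    stop_geometry("union region is empty on the valid slices")
  dd_max <- if (any(sel_delta)) max(dd$values[sel_delta]) else 0
  dd_mean <- mean(dd$values[sel_uni])
  structure(list(name = if (is.null(name)) NA_character_ else name,
                 kind = dd$kind, n_analysed = dd$n_analysed,
                 m = length(masks),
                 dd_max_mm = dd_max, dd_mean_mm = dd_mean,
                 n_voxels_union = sum(sel_uni),
                 n_voxels_disagreement = sum(sel_delta),
                 valid_slices = dd$valid_slices),
            class = "dd_summary")
}

#' @export
print.dd_summary <- function(x, ...) {
  cat(sprintf("Distance deviation summary%s (%s, N = %d, M = %d)\n",
              if (is.na(x$name)) "" else sprintf(" for '%s'", x$name),
              x$kind, x$n_analysed, x$m))
  cat(sprintf("  DD_max  = %.3f mm (over %d disagreement voxels)\n",
              x$dd_max_mm, x$n_voxels_disagreement))
  cat(sprintf("  DD_mean = %.3f mm (over %d union voxels)\n",
              x$dd_mean_mm, x$n_voxels_union))
  invisible(x)
}

#' One-row data frame form of a deviation summary
#'
#' @param x a `dd_summary`.
#' @param ... unused.
#' @return A one-row `data.frame` suitable for CSV reports.
#' @export
as.data.frame.dd_summary <- function(x, ...) {
  data.frame(name = x$name, kind = x$kind, n_analysed = x$n_analysed,
             m = x$m, dd_max_mm = x$dd_max_mm, dd_mean_mm = x$dd_mean_mm,
             n_voxels_union = x$n_voxels_union,
             n_voxels_disagreement = x$n_voxels_disagreement,
             stringsAsFactors = FALSE)
}
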