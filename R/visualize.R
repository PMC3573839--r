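#' Colour-coding specification for deviation rendering
#'
#' Deviation maps are rendered in HSV colour space: the underlying medical
#' image keeps its familiar grayscale appearance as the value (V) channel,
#' while contour disagreement is coded as hue (H) — blue for 0 mm ramping to
#' red at `cap_mm`, traversed through cyan/green/yellow. Deviations beyond
#' the cap get a distinct dark-purple colour; saturation is a fixed chroma
#' level chosen to keep both channels legible.
#'
#' @param cap_mm deviation at which the ramp saturates, mm (> 0).
#' @param hue_low,hue_high hue angles in degrees (0-360) for 0 mm and for
#'   `cap_mm`.
#' @param saturation chroma in (0, 1] used wherever a deviation is defined.
#' @param over_cap_color RGB triple in 0-1 for deviations above the cap.
#' @return An object of class `overlay_spec`.
#' @export
overlay_spec <- function(cap_mm = 5, hue_low = 240, hue_high = 0,
                         saturation = 0.8,
                         over_cap_color = c(0.25, 0, 0.35)) {
  if (!is.numeric(cap_mm) || cap_mm <= 0)
    stop_config("cap_mm must be > 0")
  if (hue_low < 0 || hue_low >= 360 || hue_high < 0 || hue_high >= 360)
    stop_config("hues must lie in [0, 360)")
  if (saturation <= 0 || saturation > 1)
    stop_config("saturation must be in (0, 1]")
  over_cap_color <- as.numeric(over_cap_color)
  if (length(over_cap_color) != 3L || any(over_cap_color < 0 | over_cap_color > 1))
    stop_config("over_cap_color must be an RGB triple in [0, 1]")
  structure(list(cap_mm = cap_mm, hue_low = hue_low, hue_high = hue_high,
                 saturation = saturation, over_cap_color = over_cap_color),
            class = "overlay_spec")
}

# hue (degrees) for a clamped deviation value; linear blue -> red ramp
dd_to_hue <- function(v, spec) {
  t <- pmin(v, spec$cap_mm) / spec$cap_mm
  spec$hue_low + t * (spec$hue_high - spec$hue_low)
}

# hsv channels (vectors) -> n x 3 rgb matrix in 0-1, exact arithmetic
# (grDevices::hsv() quantizes through 8-bit hex strings)
hsv_to_rgb <- function(h, s, v) {
  c_ <- v * s
  hp <- (h %% 360) / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  sector <- floor(hp) %% 6
  r <- g <- b <- numeric(length(hp))
  idx <- function(k) sector == k
  r[idx(0)] <- c_[idx(0)]; g[idx(0)] <- x[idx(0)]
  r[idx(1)] <- x[idx(1)];  g[idx(1)] <- c_[idx(1)]
  g[idx(2)] <- c_[idx(2)]; b[idx(2)] <- x[idx(2)]
  g[idx(3)] <- x[idx(3)];  b[idx(3)] <- c_[idx(3)]
  r[idx(4)] <- x[idx(4)];  b[idx(4)] <- c_[idx(4)]
  r[idx(5)] <- c_[idx(5)]; b[idx(5)] <- x[idx(5)]
  m <- v - c_
  cbind(r + m, g + m, b + m, deparse.level = 0)
}

#' Render a deviation overlay on a grayscale slice
#'
#' Produces an RGB image of one slice: the grayscale intensity becomes the
#' HSV value channel, and the deviation at each voxel is coded as hue from
#' `hue_low` (0 mm) to `hue_high` (`cap_mm`); deviations above the cap are
#' painted in the spec's over-cap colour, and voxels where the deviation is
#' undefined stay pure grayscale.
#'
#' @param image_slice numeric nx x ny matrix of grayscale intensities
#'   (same in-plane shape as the deviation image).
#' @param dd a `deviation_image`.
#' @param slice 0-based slice index.
#' @param spec an [overlay_spec()].
#' @param window optional `c(low, high)` intensity window; defaults to the
#'   1st-99th percentile of `image_slice`. Pass a per-volume window so one
#'   bright slice does not dim the others.
#' @return RGB array `[ny, nx, 3]` in 0-1, rows running down the image
#'   (row 1 = smallest y = anterior).
#' @export
render_overlay <- function(image_slice, dd, slice, spec = overlay_spec(),
                           window = NULL) {
  g <- dd$grid
  image_slice <- as.matrix(image_slice)
  if (!all(dim(image_slice) == g$shape[1:2]))
    stop_geometry(sprintf(
      "image slice is %d x %d but the deviation grid is %d x %d",
      dim(image_slice)[1], dim(image_slice)[2], g$shape[1], g$shape[2]))
  if (any(!is.finite(image_slice)))
    stop_geometry("grayscale intensities must be finite")
  if (is.null(window))
    window <- stats::quantile(image_slice, c(0.01, 0.99), names = FALSE)
  rng <- window[2] - window[1]
  val <- if (rng > 0) pmin(pmax((image_slice - window[1]) / rng, 0), 1)
         else array(0.5, dim = dim(image_slice)) # flat image: mid-gray

  ddm <- dd$values[, , slice + 1L]
  dim(ddm) <- g$shape[1:2]
  valid <- !is.na(ddm)
  h <- matrix(0, g$shape[1], g$shape[2])
  h[valid] <- dd_to_hue(ddm[valid], spec)
  s <- ifelse(valid, spec$saturation, 0)
  rgbm <- hsv_to_rgb(as.vector(h), as.vector(s), as.vector(val))
  over <- valid & ddm > spec$cap_mm
  rgbm[as.vector(over), ] <- rep(spec$over_cap_color, each = sum(over))

  out <- array(0, dim = c(g$shape[2], g$shape[1], 3))
  for (ch in 1:3)
    out[, , ch] <- t(matrix(rgbm[, ch], g$shape[1], g$shape[2]))
  out
}

#' Render the slice-by-angle heatmap
#'
#' One pixel per (slice, angle-bin) cell, coloured with the same ramp as the
#' overlays (value channel fixed at 1); missing cells are white, cells above
#' the cap use the over-cap colour. Row 1 is slice 0; the column order runs
#' over bin centres from just above -180 to +180 degrees, so 0 degrees
#' (anterior) sits at the horizontal centre.
#'
#' @param mat matrix from [assemble_matrix()].
#' @param spec an [overlay_spec()].
#' @return RGB array `[nrow(mat), ncol(mat), 3]` in 0-1.
#' @export
render_angular_heatmap <- function(mat, spec = overlay_spec()) {
  if (!is.matrix(mat) || length(mat) == 0L)
    stop_config("angular matrix must be a non-empty matrix")
  v <- as.vector(mat)
  out <- matrix(1, length(v), 3)          # missing -> white
  ok <- !is.na(v)
  if (any(ok))
    out[ok, ] <- hsv_to_rgb(dd_to_hue(v[ok], spec),
                            rep(spec$saturation, sum(ok)), rep(1, sum(ok)))
  over <- ok & v > spec$cap_mm
  if (any(over)) out[over, ] <- rep(spec$over_cap_color, each = sum(over))
  img <- array(0, dim = c(nrow(mat), ncol(mat), 3))
  for (ch in 1:3) img[, , ch] <- matrix(out[, ch], nrow(mat), ncol(mat))
  img
}

#' Write an RGB array as PNG
#'
#' @param img RGB array `[rows, cols, 3]` in 0-1.
#' @param path output path.
#' @param scale integer pixel-replication factor (enlarges small heatmaps).
#' @return `path`, invisibly.
#' @export
write_png_image <- function(img, path, scale = 1) {
  scale <- as.integer(scale)
  if (scale > 1L) {
    up <- array(0, dim = c(dim(img)[1] * scale, dim(img)[2] * scale, 3))
    for (ch in 1:3)
      up[, , ch] <- img[rep(seq_len(dim(img)[1]), each = scale),
                        rep(seq_len(dim(img)[2]), each = scale), ch]
    img <- up
  }
  png::writePNG(img, path)
  invisible(path)
}
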