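# Independent geometric oracles, coded separately from the package paths
# they check.

# closed polygon from a radial function, for building test shapes directly
oracle_radial_poly <- function(center, rfun, nv = 360) {
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  r <- rfun(th)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# dense boundary samples of a polygon (vertices plus interpolated points)
oracle_sample_boundary <- function(poly, step = 0.05) {
  n <- nrow(poly)
  pts <- NULL
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    t <- t[-length(t)]
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  pts
}

# brute-force symmetric Hausdorff distance between two point sets
oracle_hausdorff <- function(p, q) {
  # chunked to keep the distance matrix small
  directed <- function(a, b) {
    worst <- 0
    idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / 500))
    for (ii in idx) {
      d2 <- outer(a[ii, 1], b[, 1], `-`)^2 + outer(a[ii, 2], b[, 2], `-`)^2
      worst <- max(worst, max(sqrt(apply(d2, 1, min))))
    }
    worst
  }
  max(directed(p, q), directed(q, p))
}

# brute-force min distance from a point to polygon edges
oracle_point_poly_dist <- function(pt, poly) {
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    e <- b - a
    t <- max(0, min(1, sum((pt - a) * e) / sum(e * e)))
    best <- min(best, sqrt(sum((pt - a - t * e)^2)))
  }
  best
}

# grids/structures used across tests
unit_grid <- function(n = 6, nz = 1, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_grid(origin = origin, spacing = spacing, shape = c(n, n, nz))
}

square_structure <- function(lo = 0, hi = 4, slice = 0, name = "square") {
  structure_contours(name, stats::setNames(list(list(
    rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi)))), as.character(slice)))
}

circle_structure <- function(r, center = c(0, 0), nv = 720, slice = 0,
                             name = "circle", role = "analysed") {
  structure_contours(name, stats::setNames(list(list(
    oracle_radial_poly(center, function(th) rep(r, length(th)), nv))),
    as.character(slice)), role = role)
}

# a centred grid with 1 mm in-plane spacing covering +/- half mm
centered_grid <- function(half, nz = 1, dz = 3) {
  n <- 2L * as.integer(ceiling(half)) + 1L
  image_grid(origin = c(-(n - 1) / 2, -(n - 1) / 2, 0),
             spacing = c(1, 1, dz), shape = c(n, n, nz))
}

# random star/ellipse/annulus fixtures for oracle sweeps
random_shape_fixture <- function(seed) {
  set.seed(seed)
  kind <- sample(c("star", "ellipse", "annulus"), 1)
  spec <- switch(kind,
    star = fixture_spec("star", radius = runif(1, 8, 14),
                        n_spikes = sample(3:7, 1),
                        spike_depth = runif(1, 1, 4), n_vertices = 360),
    ellipse = fixture_spec("ellipse",
                           semi_axes = c(runif(1, 8, 15), runif(1, 5, 10)),
                           n_vertices = 360),
    annulus = fixture_spec("annulus", radius = runif(1, 8, 14),
                           n_vertices = 360))
  make_fixture(spec)
}
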