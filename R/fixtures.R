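#' Specification of a synthetic contour fixture
#'
#' Deterministic generators covering the geometric regimes that matter for
#' contour-comparison testing: plain circles and ellipses, star shapes with
#' pronounced extremes, annuli with a void interior, congruent offset pairs,
#' and multi-observer families of radially perturbed circles around a
#' reference.
#'
#' @param kind one of `"circle"`, `"ellipse"`, `"star"`, `"annulus"`,
#'   `"offset_pair"`, `"perturbed_family"`.
#' @param radius circle/star base radius, mm (also the offset-pair and
#'   perturbed-family base shape).
#' @param semi_axes `c(a, b)` ellipse semi-axes, mm.
#' @param n_spikes,spike_depth star modulation: radius `r(theta) = radius +
#'   spike_depth * cos(n_spikes * theta)`; `spike_depth < radius`.
#' @param offset `c(dx, dy)` translation of the second member of an offset
#'   pair, mm.
#' @param sigma per-observer radial perturbation SD, mm (perturbed family).
#' @param n_observers number of analysed observers N (perturbed family).
#' @param per_vertex logical; if `TRUE` the perturbed family adds a smooth
#'   low-order Fourier deformation per observer on top of the constant
#'   radial offset (more realistic, no longer analytically flat).
#' @param n_vertices vertices per polygon (>= 16; default 720).
#' @param seed RNG seed; mandatory for stochastic kinds.
#' @param center in-plane centre of the shapes, mm.
#' @param slices 0-based slice indices to contour; default the middle slice.
#' @param grid an [image_grid()], or `NULL` to build one that covers the
#'   shapes with an 8 mm margin at 1 x 1 x 3 mm spacing.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, radius = 10, semi_axes = c(12, 8),
                         n_spikes = 5, spike_depth = 3, offset = c(3, 0),
                         sigma = 1.5, n_observers = 5, per_vertex = FALSE,
                         n_vertices = 720, seed = NULL, center = c(0, 0),
                         slices = NULL, grid = NULL) {
  kinds <- c("circle", "ellipse", "star", "annulus", "offset_pair",
             "perturbed_family")
  if (!kind %in% kinds)
    stop_config(sprintf("unknown fixture kind '%s'", kind))
  bad <- character()
  if (n_vertices < 16) bad <- c(bad, "n_vertices must be >= 16")
  if (kind %in% c("circle", "star", "offset_pair", "perturbed_family") &&
      radius <= 0) bad <- c(bad, "radius must be > 0")
  if (kind == "ellipse" && any(semi_axes <= 0))
    bad <- c(bad, "semi_axes must be > 0")
  if (kind == "star") {
    if (n_spikes < 1) bad <- c(bad, "n_spikes must be >= 1")
    if (spike_depth < 0 || spike_depth >= radius)
      bad <- c(bad, "spike_depth must be in [0, radius)")
  }
  if (kind == "annulus" && radius <= 0)
    bad <- c(bad, "radius (outer) must be > 0")
  if (kind == "perturbed_family") {
    if (sigma < 0) bad <- c(bad, "sigma must be >= 0")
    if (n_observers < 1) bad <- c(bad, "n_observers must be >= 1")
    if (is.null(seed)) bad <- c(bad, "seed is mandatory for perturbed_family")
  }
  if (length(bad))
    stop_config(paste0("invalid fixture spec: ", paste(bad, collapse = "; ")))
  structure(list(kind = kind, radius = radius, semi_axes = semi_axes,
                 n_spikes = n_spikes, spike_depth = spike_depth,
                 offset = offset, sigma = sigma, n_observers = n_observers,
                 per_vertex = per_vertex, n_vertices = n_vertices,
                 seed = seed, center = center, slices = slices, grid = grid),
            class = "fixture_spec")
}

poly_radial <- function(center, rfun, nv) {
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  r <- rfun(th)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

fixture_extent <- function(spec) {
  switch(spec$kind,
    circle = spec$radius,
    ellipse = max(spec$semi_axes),
    star = spec$radius + spec$spike_depth,
    annulus = spec$radius,
    offset_pair = spec$radius + max(abs(spec$offset)),
    perturbed_family = spec$radius + 5 * max(spec$sigma, 0.5))
}

default_fixture_grid <- function(extent, center, margin = 8, nz = 3) {
  half <- extent + margin
  n <- as.integer(2 * ceiling(half) + 1)
  image_grid(origin = c(center[1] - (n - 1) / 2, center[2] - (n - 1) / 2, 0),
             spacing = c(1, 1, 3), shape = c(n, n, nz))
}

#' Generate a synthetic contour fixture
#'
#' Builds the structures described by a [fixture_spec()] on its grid. All
#' randomness flows from the spec's seed through a private RNG stream, so a
#' given spec always yields vertex-identical output. For
#' `"perturbed_family"` the result contains one reference circle (role
#' `"reference"`) plus N observer contours with radius `radius + eps_i`,
#' `eps_i ~ Normal(0, sigma)` drawn once per contour (a constant radial
#' offset, so the deviation field is analytically the SD of the offsets);
#' the drawn offsets are attached as attribute `"offsets"`.
#'
#' @param spec a [fixture_spec()].
#' @return A `contour_set` (structures + grid).
#' @export
make_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec"))
    stop_config("make_fixture expects a fixture_spec")
  center <- spec$center
  nv <- spec$n_vertices
  grid <- spec$grid
  if (is.null(grid))
    grid <- default_fixture_grid(fixture_extent(spec), center)
  slices <- spec$slices
  if (is.null(slices)) slices <- (grid$shape[3] - 1L) %/% 2L
  on_slices <- function(polys) {
    sl <- stats::setNames(rep(list(polys), length(slices)),
                          as.character(slices))
    sl
  }
  offsets <- NULL
  structs <- switch(spec$kind,
    circle = list(structure_contours("circle", on_slices(list(
      poly_radial(center, function(th) rep(spec$radius, length(th)), nv))))),
    ellipse = list(structure_contours("ellipse", on_slices(list(
      cbind(center[1] + spec$semi_axes[1] * cos(seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]),
            center[2] + spec$semi_axes[2] * sin(seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)])))))),
    star = list(structure_contours("star", on_slices(list(
      poly_radial(center, function(th)
        spec$radius + spec$spike_depth * cos(spec$n_spikes * th), nv))))),
    annulus = {
      inner <- spec$radius / 2
      list(structure_contours("annulus", on_slices(list(
        poly_radial(center, function(th) rep(spec$radius, length(th)), nv),
        poly_radial(center, function(th) rep(inner, length(th)), nv)))))
    },
    offset_pair = {
      base <- poly_radial(center, function(th) rep(spec$radius, length(th)), nv)
      moved <- sweep(base, 2, spec$offset, `+`)
      list(structure_contours("shape_a", on_slices(list(base))),
           structure_contours("shape_b", on_slices(list(moved))))
    },
    perturbed_family = {
      n <- spec$n_observers
      draws <- with_seed(spec$seed, {
        eps <- stats::rnorm(n, 0, spec$sigma)
        four <- if (spec$per_vertex)
          replicate(n, list(amp = stats::rnorm(3, 0, spec$sigma / 3),
                            phase = stats::runif(3, 0, 2 * pi)),
                    simplify = FALSE)
        else NULL
        list(eps = eps, four = four)
      })
      offsets <- draws$eps
      ref <- structure_contours("reference", on_slices(list(
        poly_radial(center, function(th) rep(spec$radius, length(th)), nv))),
        role = "reference")
      obs <- lapply(seq_len(n), function(i) {
        rfun <- function(th) {
          r <- rep(spec$radius + draws$eps[i], length(th))
          if (spec$per_vertex) {
            f <- draws$four[[i]]
            for (k in 1:3) r <- r + f$amp[k] * cos(k * th + f$phase[k])
          }
          r
        }
        structure_contours(sprintf("observer_%02d", i),
                           on_slices(list(poly_radial(center, rfun, nv))))
      })
      c(list(ref), obs)
    })
  out <- structure(list(structures = structs, grid = grid),
                   class = "contour_set")
  if (!is.null(offsets)) attr(out, "offsets") <- offsets
  out
}
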