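# distance images with hand-set values, for direct formula checks
fake_distance <- function(vals, g, slices = 0L) {
  contourdev:::new_distance_image(array(vals, dim = g$shape), g, "slice2d",
                                  slices)
}

test_that("pairwise deviation is the absolute difference and is symmetric", {
  g <- unit_grid(3)
  d1 <- fake_distance(3, g)
  d2 <- fake_distance(5, g)
  expect_true(all(dd_pair(d1, d2)$values == 2))
  expect_identical(dd_pair(d1, d2)$values, dd_pair(d2, d1)$values)

  # identical contours: zero everywhere
  gg <- centered_grid(12)
  da <- signed_distance_fast(circle_structure(8), gg)
  expect_true(all(dd_pair(da, da)$values[, , 1] == 0))
})

test_that("concentric circles give a constant 2 mm pair deviation (exact path)", {
  g <- centered_grid(18)
  d1 <- signed_distance_exact(circle_structure(10), g)
  d2 <- signed_distance_exact(circle_structure(12), g)
  v <- dd_pair(d1, d2)$values[, , 1]
  expect_equal(mean(v), 2, tolerance = 0.01)
  expect_true(all(abs(v - 2) < 0.01))
})

test_that("reference RMS deviation reduces correctly and handles signs", {
  g <- unit_grid(3)
  dr <- fake_distance(1, g)
  dp <- fake_distance(3, g)   # +2 from reference
  dm <- fake_distance(-1, g)  # -2 from reference

  # N = 1 is bit-exact dd_pair
  gg <- centered_grid(12)
  a <- signed_distance_fast(circle_structure(8), gg)
  b <- signed_distance_fast(circle_structure(6), gg)
  expect_identical(dd_vs_reference(list(a), b)$values, dd_pair(a, b)$values)
  expect_identical(dd_vs_reference(list(a), b)$kind, "pair")

  # RMS of {+2, -2} is 2
  r <- dd_vs_reference(list(dp, dm), dr)
  expect_true(all(r$values == 2))
  expect_identical(r$kind, "vs_reference")
  expect_identical(r$n_analysed, 2L)

  # all equal to reference: zero
  expect_true(all(dd_vs_reference(list(dr, dr, dr), dr)$values == 0))
  expect_error(dd_vs_reference(list(), dr), class = "cdv_config_error")
})

test_that("std deviation uses the population formula around the mean image", {
  g <- unit_grid(3)
  ds <- lapply(c(2, 4, 6), fake_distance, g = g)
  expect_equal(unique(as.vector(dd_std(ds)$values)), sqrt(8 / 3),
               tolerance = 1e-12)
  # sample variant divides by N - 1
  expect_equal(unique(as.vector(dd_std(ds, sample = TRUE)$values)), 2,
               tolerance = 1e-12)
  # N identical images: zero
  expect_true(all(dd_std(list(ds[[1]], ds[[1]], ds[[1]]))$values == 0))
  expect_error(dd_std(list(ds[[1]])), "at least two",
               class = "cdv_config_error")
  # invariant to input ordering
  expect_identical(dd_std(ds)$values, dd_std(rev(ds))$values)
})

test_that("std of two images equals half the pair deviation voxelwise", {
  gg <- centered_grid(14)
  a <- signed_distance_fast(circle_structure(9), gg)
  b <- signed_distance_fast(make_fixture(fixture_spec("star", radius = 8,
         spike_depth = 2, grid = gg, slices = 0))$structures[[1]], gg)
  expect_equal(dd_std(list(a, b))$values, dd_pair(a, b)$values / 2,
               tolerance = 1e-12)
})

test_that("perturbed circle family recovers the std of the drawn offsets", {
  fam <- make_fixture(fixture_spec("perturbed_family", radius = 20,
                                   sigma = 1.5, n_observers = 20, seed = 11))
  eps <- attr(fam, "offsets")
  dis <- lapply(fam$structures[-1], signed_distance_fast, grid = fam$grid)
  dds <- dd_std(dis)
  k <- dds$valid_slices + 1L
  pop_sd <- sqrt(mean((eps - mean(eps))^2))
  v <- dds$values[, , k]
  # D_i(x) = |x - c| - 20 - eps_i, so DD_S is the population SD of eps
  # everywhere (up to raster tolerance near the contours)
  expect_equal(stats::median(v), pop_sd, tolerance = 0.2)
  expect_gt(mean(abs(v - pop_sd) < 0.75), 0.99)
})

test_that("disagreement region covers some-but-not-all voxels", {
  g <- unit_grid(8)
  mk <- function(lo, hi) rasterize(square_structure(lo, hi), g)
  m1 <- mk(0, 3); m2 <- mk(0, 5); m3 <- mk(0, 6)
  delta <- disagreement_region(list(m1, m2, m3))
  expect_false(delta$values[2, 2, 1])   # inside all three
  expect_false(delta$values[8, 8, 1])   # inside none
  expect_true(delta$values[5, 1, 1])    # inside m2, m3 only
  expect_true(delta$values[7, 1, 1])    # inside m3 only
  # identical masks: empty region
  expect_identical(sum(disagreement_region(list(m1, m1))$values), 0L)
})

test_that("disagreement of concentric circles is the analytic annulus", {
  g <- centered_grid(16)
  m1 <- rasterize(circle_structure(10), g)
  m2 <- rasterize(circle_structure(12), g)
  delta <- disagreement_region(list(m1, m2))$values[, , 1]
  xs <- contourdev:::axis_coords(g, 1)
  d <- sqrt(outer(xs^2, xs^2, `+`))
  expect_true(all(delta[d > 10.75 & d < 11.25]))
  expect_false(any(delta[d < 9.25 | d > 12.75]))
})

test_that("union region is the voxelwise OR", {
  g <- unit_grid(10)
  m1 <- rasterize(square_structure(0, 3), g)
  m2 <- rasterize(square_structure(6, 9), g)
  expect_identical(union_region(list(m1))$values, m1$values)
  u <- union_region(list(m1, m2))
  expect_identical(sum(u$values), sum(m1$values) + sum(m2$values)) # disjoint
  # nested circles: union equals the outer mask
  gg <- centered_grid(14)
  mo <- rasterize(circle_structure(10), gg)
  mi <- rasterize(circle_structure(5), gg)
  expect_identical(union_region(list(mo, mi))$values, mo$values)
})

test_that("scalar summary matches Hausdorff for an offset square pair", {
  g <- image_grid(c(-16, -16, 0), c(1, 1, 3), c(40, 40, 1))
  s1 <- square_structure(-10, 10)
  s2 <- structure_contours("sq2", list("0" = list(
    rbind(c(-7, -10), c(13, -10), c(13, 10), c(-7, 10)))))
  d1 <- signed_distance_fast(s1, g); d2 <- signed_distance_fast(s2, g)
  m1 <- rasterize(s1, g); m2 <- rasterize(s2, g)
  summ <- summarize_deviation(dd_pair(d1, d2), list(m1, m2))
  h <- oracle_hausdorff(
    oracle_sample_boundary(s1$slices[["0"]][[1]]),
    oracle_sample_boundary(s2$slices[["0"]][[1]]))
  expect_equal(h, 3, tolerance = 0.06)          # oracle sanity
  expect_equal(summ$dd_max_mm, h, tolerance = sqrt(2))
  expect_gte(summ$dd_max_mm, summ$dd_mean_mm)
})

test_that("constant deviation over the union averages to itself; zero case", {
  g <- centered_grid(16)
  m1 <- rasterize(circle_structure(10), g)
  m2 <- rasterize(circle_structure(12), g)
  dd <- contourdev:::new_deviation_image(array(1.5, dim = g$shape), g,
                                         "slice2d", "pair", 1L, 0L)
  summ <- summarize_deviation(dd, list(m1, m2))
  expect_identical(summ$dd_mean_mm, 1.5)
  expect_identical(summ$dd_max_mm, 1.5)

  # identical contours: dd_max = dd_mean = 0 (empty disagreement region)
  da <- signed_distance_fast(circle_structure(10), g)
  z <- summarize_deviation(dd_pair(da, da), list(m1, m1))
  expect_identical(z$dd_max_mm, 0)
  expect_identical(z$dd_mean_mm, 0)
  expect_identical(z$n_voxels_disagreement, 0L)

  # empty union region on the valid slices errors
  gg <- image_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 2))
  em <- structure(list(values = array(FALSE, dim = gg$shape), grid = gg,
                       contoured_slices = 0L), class = "binary_mask")
  dz <- contourdev:::new_deviation_image(array(0, dim = gg$shape), gg,
                                         "slice2d", "pair", 1L, 0L)
  expect_error(summarize_deviation(dz, list(em, em)), "union",
               class = "cdv_geometry_error")
})

test_that("deviations outside the union and inside the intersection never exceed the disagreement maximum", {
  for (seed in c(3, 14, 25)) {
    set.seed(seed)
    g <- centered_grid(20)
    specs <- list(
      fixture_spec("circle", radius = runif(1, 7, 11), grid = g, slices = 0),
      fixture_spec("star", radius = runif(1, 7, 10), n_spikes = sample(3:6, 1),
                   spike_depth = runif(1, 1, 3), grid = g, slices = 0),
      fixture_spec("ellipse", semi_axes = c(runif(1, 8, 12), runif(1, 5, 8)),
                   grid = g, slices = 0))
    ss <- lapply(specs, function(sp) make_fixture(sp)$structures[[1]])
    ds <- lapply(ss, signed_distance_fast, grid = g)
    ms <- lapply(ss, rasterize, grid = g)
    delta <- disagreement_region(ms)$values
    uni <- union_region(ms)$values
    inter <- Reduce(`&`, lapply(ms, `[[`, "values"))
    for (dd in list(dd_pair(ds[[1]], ds[[2]]), dd_std(ds))) {
      v <- dd$values
      mx <- max(v[delta])
      if (any(!uni)) expect_lte(max(v[!uni]), mx)
      if (any(inter)) expect_lte(max(v[inter]), mx)
    }
  }
})

test_that("mean deviation can violate the triangle inequality (found by search)", {
  # Three single-slice structures: a circle on the right (A), a two-blob
  # structure spanning both sides (B), and a circle on the left (C). The
  # union domain of each pairwise mean differs, which breaks metricity:
  # dd_mean(A, C) > dd_mean(A, B) + dd_mean(B, C).
  g <- image_grid(c(-30, -30, 0), c(1, 1, 3), c(61, 61, 1))
  circ <- function(cx, r) oracle_radial_poly(c(cx, 0),
                                             function(th) rep(r, length(th)), 180)
  A <- structure_contours("A", list("0" = list(circ(13.3, 6.94))))
  B <- structure_contours("B", list("0" = list(circ(-19.6, 3.06),
                                               circ(9.93, 3.45))))
  C <- structure_contours("C", list("0" = list(circ(-11.7, 10.7))))
  pre <- lapply(list(A, B, C), function(s)
    list(d = signed_distance_fast(s, g), m = rasterize(s, g)))
  dm <- function(i, j)
    summarize_deviation(dd_pair(pre[[i]]$d, pre[[j]]$d),
                        list(pre[[i]]$m, pre[[j]]$m))$dd_mean_mm
  expect_gt(dm(1, 3), dm(1, 2) + dm(2, 3))
})

test_that("statistics are restricted to slices contoured by all inputs", {
  g <- image_grid(c(-16, -16, 0), c(1, 1, 3), c(33, 33, 4))
  s1 <- structure_contours("a", list(
    "1" = list(oracle_radial_poly(c(0, 0), function(th) rep(8, length(th)), 180)),
    "2" = list(oracle_radial_poly(c(0, 0), function(th) rep(8, length(th)), 180))))
  s2 <- structure_contours("b", list(
    "1" = list(oracle_radial_poly(c(0, 0), function(th) rep(10, length(th)), 180))))
  d1 <- signed_distance_fast(s1, g); d2 <- signed_distance_fast(s2, g)
  dd <- dd_pair(d1, d2)
  expect_identical(dd$valid_slices, 1L)
  expect_true(all(is.na(dd$values[, , c(1, 3, 4)])))
  summ <- summarize_deviation(dd, list(rasterize(s1, g), rasterize(s2, g)))
  expect_equal(summ$dd_max_mm, 2, tolerance = sqrt(2))
})
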