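# Rasterization, DVH curves and metric evaluation.

test_that("box mask volume matches the brute-force oracle and the analytic value", {
  s <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(20, 20, 20), 2),
                      "box", 1L)
  g <- small_grid()
  m <- rasterize_structure(s, g, supersample = 1L)
  w <- oracle_voxel_weights(s, g)
  expect_equal(sum(m$occupancy * m$voxel_volume), sum(w), tolerance = 1e-12)
  # within one voxel layer per face of 8000 mm^3
  expect_lt(abs(mask_volume(m) - 8000), 6 * 20 * 20 * 1)
})

test_that("multiple polygons on one plane combine by the even-odd rule", {
  z <- 0
  outer <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10), z)
  inner <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5), z)
  annulus <- rt_structure("annulus", 1L, list(outer, inner))
  g <- small_grid(shape = c(25, 25, 3), origin = c(-12, -12, -1))
  m <- rasterize_structure(annulus, g, supersample = 1L)
  ix0 <- 13; iz0 <- 2  # voxel centred at (0, 0, 0)
  expect_equal(m$occupancy[ix0, ix0, iz0], 0)     # strictly inside the hole
  expect_gt(m$occupancy[ix0 + 8, ix0, iz0], 0)    # in the ring (x = 8)
  expect_equal(m$occupancy[ix0 + 12, ix0, iz0], 0) # outside (x = 12)
})

test_that("rasterized sphere volume converges to the analytic volume", {
  s <- make_structure(phantom_spec("SPHERE", c(0, 0, 0), 10, 2), "sph", 1L)
  g <- small_grid(shape = c(29, 29, 29), origin = c(-14, -14, -14))
  m4 <- rasterize_structure(s, g, supersample = 4L)
  expect_lt(abs(mask_volume(m4) - s$analytic_volume_mm3) /
              s$analytic_volume_mm3, 0.02)
  # supersampling refines the estimate
  m1 <- rasterize_structure(s, g, supersample = 1L)
  expect_lte(abs(mask_volume(m4) - s$analytic_volume_mm3),
             abs(mask_volume(m1) - s$analytic_volume_mm3) + 1e-9)
})

test_that("contours far from every grid plane and empty masks raise", {
  s <- make_structure(phantom_spec("BOX", c(0, 0, 200), c(10, 10, 10), 2),
                      "faraway", 1L)
  g <- small_grid(shape = c(25, 25, 5), origin = c(-12, -12, -2))
  expect_error(rasterize_structure(s, g), class = "rtqa_out_of_grid")

  tiny <- make_structure(phantom_spec("BOX", c(100, 100, 0), c(4, 4, 4), 2),
                         "outside_xy", 1L)
  expect_error(rasterize_structure(tiny, g),
               class = "rtqa_degenerate_structure")
})

test_that("uniform-field DVH is the exact step function", {
  s <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(16, 16, 16), 2),
                      "box", 1L)
  g <- small_grid(dose_field_spec("UNIFORM", level = 20))
  dvh <- compute_dvh(rasterize_structure(s, g), g)
  expect_true(all(dvh$cum_volume_pct[dvh$dose_edges <= 20] == 100))
  expect_true(all(dvh$cum_volume_pct[dvh$dose_edges > 20] == 0))
  expect_equal(as.numeric(evaluate_metric(dvh, "Dmean")), 20)
  expect_equal(as.numeric(evaluate_metric(dvh, "D50%")), 20)
  expect_equal(as.numeric(evaluate_metric(dvh, "V20Gy")), 100)
  expect_equal(as.numeric(evaluate_metric(dvh, "V20.1Gy")), 0)
})

test_that("linear-gradient DVH over a box matches the closed form", {
  # box spanning x in [-10, 10], dose d(x) = 1 + 0.1 x in [0, 2]:
  # V(d) = 100 * (10 - (d - 1) / 0.1) / 20 for d in (0, 2]
  s <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(20, 20, 20), 2),
                      "box", 1L)
  g <- small_grid(dose_field_spec("LINEAR_X", gradient = 0.1, intercept = 1))
  dvh <- compute_dvh(rasterize_structure(s, g), g, bin_width = 0.01)
  sel <- dvh$dose_edges > 0.05 & dvh$dose_edges <= 1.95
  d <- dvh$dose_edges[sel]
  closed_form <- 100 * (10 - (d - 1) / 0.1) / 20
  # one voxel layer of the 21-column box is 100 / 21 < 5 percentage points
  layer_pct <- 100 / 21
  expect_lt(max(abs(dvh$cum_volume_pct[sel] - closed_form)), layer_pct + 1e-9)
  expect_true(all(diff(dvh$cum_volume_pct) <= 1e-12))
})

test_that("metrics on a two-atom distribution follow the stated conventions", {
  curve <- structure(list(structure_name = "toy",
                          dose_edges = seq(0, 31, by = 1),
                          cum_volume_pct = NULL,
                          total_volume_cc = 1,
                          doses = c(10, 30), weights = c(500, 500)),
                     class = "rt_dvh")
  expect_equal(as.numeric(evaluate_metric(curve, "Dmean")), 20)
  expect_equal(as.numeric(evaluate_metric(curve, "Dmax")), 30)
  expect_equal(as.numeric(evaluate_metric(curve, "Dmin")), 10)
  # hottest 50% is exactly the 30 Gy half
  expect_equal(as.numeric(evaluate_metric(curve, "D50%")), 30)
  expect_equal(as.numeric(evaluate_metric(curve, "D25%")), 30)
  # linear interpolation inside the sorted-dose step
  expect_equal(as.numeric(evaluate_metric(curve, "D75%")), 20)
  expect_equal(as.numeric(evaluate_metric(curve, "D100%")), 10)
  # Dx cc converts through the total volume (1 cc)
  expect_equal(as.numeric(evaluate_metric(curve, "D0.5cc")), 30)
  expect_error(evaluate_metric(curve, "D2cc"), class = "rtqa_domain_error")
  # V at 0 Gy is always 100%
  expect_equal(as.numeric(evaluate_metric(curve, "V0Gy")), 100)
  expect_equal(as.numeric(evaluate_metric(curve, "V10.5Gy")), 50)
  expect_equal(as.numeric(evaluate_metric(curve, metric_spec("V_GY", 10.5,
                                                             "CC"))), 0.5)
})

test_that("metric grammar parses the field's notation and rejects junk", {
  expect_identical(parse_metric("D2%")$kind, "D_PCT")
  expect_identical(parse_metric("D0.1cc")$kind, "D_CC")
  expect_identical(parse_metric("V70Gy")$kind, "V_GY")
  expect_identical(parse_metric("V70Gy[cc]")$unit_out, "CC")
  expect_identical(parse_metric("dmean")$kind, "DMEAN")
  expect_error(parse_metric("Q7"), class = "rtqa_bad_metric")
  expect_error(metric_spec("D_PCT", 0), class = "rtqa_bad_metric")
  expect_error(metric_spec("V_GY"), class = "rtqa_bad_metric")
})

test_that("volume is conserved between mask and curve", {
  set.seed(31)
  for (i in 1:5) {
    s <- random_phantom(i)
    g <- small_grid(random_field(i), origin = c(-14, -14, -14),
                    spacing = c(2, 2, 2), shape = c(15, 15, 15))
    m <- rasterize_structure(s, g)
    dvh <- compute_dvh(m, g)
    expect_equal(sum(m$occupancy) * m$voxel_volume,
                 dvh$total_volume_cc * 1000, tolerance = 1e-12)
  }
})

test_that("DVH curves are monotone and metric orderings hold on random cases", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_phantom(i)
    g <- small_grid(random_field(i + 1), origin = c(-14, -14, -14),
                    spacing = c(2, 2, 2), shape = c(15, 15, 15))
    dvh <- compute_dvh(rasterize_structure(s, g), g, bin_width = 0.05)
    expect_true(all(diff(dvh$cum_volume_pct) <= 1e-12))
    expect_equal(dvh$cum_volume_pct[1], 100)
    dmin <- as.numeric(evaluate_metric(dvh, "Dmin"))
    dmean <- as.numeric(evaluate_metric(dvh, "Dmean"))
    dmax <- as.numeric(evaluate_metric(dvh, "Dmax"))
    expect_true(dmin <= dmean + 1e-12 && dmean <= dmax + 1e-12)
    xs <- c(2, 10, 25, 50, 75, 90, 98)
    dx <- vapply(xs, function(x)
      as.numeric(evaluate_metric(dvh, metric_spec("D_PCT", x))), numeric(1))
    expect_true(all(diff(dx) <= 1e-9))
    vg <- vapply(seq(0, dmax + 1, length.out = 12), function(v)
      as.numeric(evaluate_metric(dvh, metric_spec("V_GY", v))), numeric(1))
    expect_true(all(diff(vg) <= 1e-9))
  }
})
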