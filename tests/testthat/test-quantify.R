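# An analytic stand-in library: values mimic the simulated behaviour
# (magnitude grows with diameter, decays with nodule depth and grows with
# indentation depth), letting the inversion geometry be tested without FEM.
synthetic_library <- function(depths = c(30, 40, 50),
                              diameters = c(10, 16, 22, 30),
                              ind = c(1, 5, 10)) {
  # non-separable in (depth, diameter) across indentation depths, so the
  # depth-diameter curves of different indentation depths genuinely differ
  f <- function(de, di, k) -di^(1 + 0.08 * k) * exp(-de / (10 + 2 * k)) / 500
  vals <- array(NA_real_, c(length(depths), length(diameters), length(ind)),
                dimnames = list(depth = depths, diameter = diameters,
                                indentation = ind))
  for (i in seq_along(depths)) for (j in seq_along(diameters))
    for (k in seq_along(ind))
      vals[i, j, k] <- f(depths[i], diameters[j], ind[k])
  structure(list(diameters = diameters, depths = depths,
                 indentation_depths = ind, values = vals,
                 provenance = list(smoothing = 0),
                 forward = f),
            class = "calibration_library")
}

test_that("equivalent radius follows the volume and area formulas", {
  expect_equal(signif(equivalent_radius(20 * 12 * 12), 3), 8.83)
  expect_equal(equivalent_radius(4 * pi / 3), 1)
  expect_equal(equivalent_radius_2d(pi * 25), 5)
  expect_error(equivalent_radius(-1), "positive")
  expect_error(equivalent_radius_2d(0), "positive")
})

test_that("quantification errors reproduce the phantom validation numbers", {
  mk <- function(r) structure(list(
    chosen = c(depth = 10, diameter = 2 * r), area = pi * r^2,
    candidates = NULL, residual = 0, equivalent_radius = r),
    class = "quantification_result")
  e1 <- quantification_errors(mk(9.05), list(depth = 10, diameter = 2 * 8.83))
  expect_equal(signif(unname(e1["size_pct"]), 2), 2.5)
  e2 <- quantification_errors(mk(9.94), list(depth = 10, diameter = 2 * 8.83))
  expect_equal(signif(unname(e2["size_pct"]), 3), 12.6)
  ed <- quantification_errors(
    structure(list(chosen = c(depth = 11, diameter = 2 * 8.83),
                   area = pi * 8.83^2, residual = 0,
                   equivalent_radius = 8.83),
              class = "quantification_result"),
    list(depth = 10, diameter = 2 * 8.83))
  expect_equal(unname(ed["depth_pct"]), 10)
  e0 <- quantification_errors(mk(8.83), list(depth = 10, diameter = 2 * 8.83))
  expect_equal(unname(e0["size_pct"]), 0)
  expect_equal(unname(e0["area_pct"]), 0)
})

test_that("inversion passes exactly through tabulated grid values", {
  lib <- synthetic_library()
  v <- lib$values[2, 3, 2]           # depth 40, diameter 22, indentation 5
  cv <- invert_to_curve(lib, v, 5)
  i40 <- which(cv$depths == 40)
  expect_equal(cv$diameters[i40], 22, tolerance = 1e-9)
})

test_that("out-of-range measurements give empty or partial curves", {
  lib <- synthetic_library()
  # zero curvature: weaker than any tabulated nodule -> empty curve
  cv0 <- invert_to_curve(lib, 0, 5)
  expect_true(cv0$empty)
  # stronger than everything: empty as well
  cvbig <- invert_to_curve(lib, min(lib$values) * 10, 5)
  expect_true(cvbig$empty)
  expect_error(invert_to_curve(lib, 0, 7), "not in the library")
})

test_that("curves through a common point intersect exactly there", {
  mk_curve <- function(ind, depths, dias)
    structure(list(indentation_depth = ind, depths = depths,
                   diameters = dias, empty = FALSE),
              class = "depth_diameter_curve")
  # three lines of different slope through (30, 16)
  d <- c(20, 30, 40)
  c1 <- mk_curve(1, d, 16 + 0.8 * (d - 30))
  c2 <- mk_curve(5, d, 16 - 0.5 * (d - 30))
  c3 <- mk_curve(10, d, 16 + 0.1 * (d - 30))
  res <- intersect_curves(list(c1, c2, c3))
  expect_equal(unname(res$chosen["depth"]), 30, tolerance = 1e-4)
  expect_equal(unname(res$chosen["diameter"]), 16, tolerance = 1e-4)
  expect_lt(res$residual, 1e-8)
  expect_equal(res$equivalent_radius, res$chosen[["diameter"]] / 2)
  expect_equal(res$area, pi * (res$chosen[["diameter"]] / 2)^2,
               tolerance = 1e-9)
})

test_that("closest approach is returned when curves do not quite meet", {
  mk_curve <- function(ind, depths, dias)
    structure(list(indentation_depth = ind, depths = depths,
                   diameters = dias, empty = FALSE),
              class = "depth_diameter_curve")
  d <- c(20, 30, 40)
  c1 <- mk_curve(1, d, 16 + 0.8 * (d - 30))
  c2 <- mk_curve(5, d, 17 - 0.5 * (d - 30))   # shifted by +1 mm
  res <- intersect_curves(list(c1, c2))
  expect_gte(res$residual, 0)
  expect_true(abs(res$chosen[["diameter"]] - 16.5) < 1.5)
  # residual ceiling triggers the inconsistency signal
  c3 <- mk_curve(10, d, rep(40, 3))
  expect_error(intersect_curves(list(c1, c3), residual_ceiling = 1e-6),
               "inconsistent")
})

test_that("empty curves abort the intersection with a clear message", {
  mk_curve <- function(ind, depths, dias, empty = FALSE)
    structure(list(indentation_depth = ind, depths = depths,
                   diameters = dias, empty = empty),
              class = "depth_diameter_curve")
  good <- mk_curve(1, c(20, 30), c(10, 12))
  bad <- mk_curve(5, numeric(0), numeric(0), empty = TRUE)
  expect_error(intersect_curves(list(good, bad)), "indentation depth 5")
})

test_that("analytic closed loop recovers a grid point with zero residual", {
  lib <- synthetic_library()
  truth <- c(depth = 40, diameter = 16)
  curves <- lapply(lib$indentation_depths, function(k)
    invert_to_curve(lib, lib$forward(truth["depth"], truth["diameter"], k),
                    k))
  res <- intersect_curves(curves)
  expect_equal(unname(res$chosen["depth"]), 40, tolerance = 1e-6)
  expect_equal(unname(res$chosen["diameter"]), 16, tolerance = 1e-6)
  expect_lt(res$residual, 1e-6)
})

test_that("library grids are validated for geometric feasibility", {
  dom <- tissue_domain(100, 100, 8)
  prot <- indentation_protocol(probe_positions(100, 7), 2)
  expect_error(
    build_library(dom, tissue_materials(), prot,
                  diameters = c(30), depths = c(10)),
    "infeasible")
  expect_error(
    build_library(dom, tissue_materials(), prot,
                  diameters = c(20, 10), depths = c(30)),
    "ascending")
})
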