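# analytic two-circle-union area (independent oracle for the discretizer)
circle_union_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(pi * r1^2 + pi * r2^2)
  if (d <= abs(r1 - r2)) return(pi * max(r1, r2)^2)
  lens <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                 (d + r1 + r2))
  pi * r1^2 + pi * r2^2 - lens
}

test_that("discretized shapes match their analytic areas", {
  circ <- make_nodule(nodule_spec("circle", depth = 30, x = 50,
                                  diameter = 16))
  expect_equal(circ$area, pi * 64, tolerance = 0.005)
  expect_equal(nodule_area(nodule_spec("circle", depth = 30, x = 50,
                                       diameter = 16)),
               201.06, tolerance = 1e-3)

  rect <- make_nodule(nodule_spec("rectangle", depth = 30, x = 50,
                                  width = 12.5, height = 25))
  expect_equal(rect$area, 312.5, tolerance = 1e-12)

  ic <- nodule_spec("intersecting_circles", depth = 30, x = 50,
                    diameters = c(10, 15), offset = 8)
  expect_equal(make_nodule(ic)$area, circle_union_area(5, 7.5, 8),
               tolerance = 0.005)
  # default offset = mean radius
  ic2 <- nodule_spec("intersecting_circles", depth = 30, x = 50,
                     diameters = c(10, 15))
  expect_equal(ic2$offset, 6.25)
  expect_equal(make_nodule(ic2)$area, circle_union_area(5, 7.5, 6.25),
               tolerance = 0.005)

  ann <- make_nodule(nodule_spec("diffuse_annulus", depth = 35, x = 50,
                                 inner_diameter = 20, outer_diameter = 30))
  expect_equal(ann$area, pi * 15^2, tolerance = 0.005)
  expect_equal(ann$core_area, pi * 10^2, tolerance = 0.005)
})

test_that("nodule specs validate shape parameters", {
  expect_error(nodule_spec("circle", depth = 30, x = 50), "missing")
  expect_error(nodule_spec("circle", depth = 30, x = 50, diameter = -2),
               "positive")
  expect_error(nodule_spec("intersecting_circles", depth = 30, x = 50,
                           diameters = c(10, 15), offset = 30), "intersect")
  expect_error(nodule_spec("diffuse_annulus", depth = 30, x = 50,
                           inner_diameter = 30, outer_diameter = 20),
               "smaller")
  bow_tie <- cbind(c(-5, 5, 5, -5), c(-5, 5, -5, 5))
  expect_error(nodule_spec("polygon", depth = 30, x = 50,
                           vertices = bow_tie), "self-intersecting")
})

test_that("depth reference conversion distinguishes top and centre", {
  top <- nodule_spec("rectangle", depth = 10, x = 50, depth_reference = "top",
                     width = 20, height = 12)
  expect_equal(palpquant:::nodule_center_y(top), 16)
  ctr <- nodule_spec("circle", depth = 30, x = 50, diameter = 16)
  expect_equal(palpquant:::nodule_center_y(ctr), 30)
  topc <- nodule_spec("circle", depth = 10, x = 50, depth_reference = "top",
                      diameter = 16)
  expect_equal(palpquant:::nodule_center_y(topc), 18)
})

test_that("the bundle registry instantiates every scenario", {
  reg <- reference_configurations()
  expect_true(all(c("insilico_example1", "insilico_example2",
                    "intersecting_circles_a", "intersecting_circles_b",
                    "irregular_polygon", "diffuse_annulus",
                    "rectangular_nodule", "gelatin_phantom_2d") %in%
                    names(reg)))
  e1 <- reg$insilico_example1
  expect_equal(e1$nodule$shape, "circle")
  expect_equal(e1$nodule$diameter, 16)
  expect_equal(e1$nodule$depth, 30)
  expect_equal(e1$protocol$depths, c(1, 5, 10))
  expect_length(e1$protocol$positions, 40)

  gp <- reg$gelatin_phantom_2d
  expect_equal(gp$nodule$depth_reference, "top")
  expect_equal(gp$nodule$depth, 10)
  expect_equal(gp$domain$height, 31)
  expect_equal(gp$protocol$depths, c(2, 4, 6))
  expect_equal(signif(young_from_c1(gp$materials$healthy), 3), 28.1)

  # every bundle passes spec validation and meshes successfully
  for (b in reg) {
    expect_s3_class(b$nodule, "nodule_spec")
    mesh <- build_mesh(b$domain, b$nodule)
    expect_s3_class(mesh, "palp_mesh")
    if (b$nodule$shape != "none")
      expect_gt(unname(mesh_label_areas(mesh)["cancerous"]), 0)
  }
})

tiny_bundle <- function() {
  list(domain = tissue_domain(60, 40, 8),
       nodule = nodule_spec("circle", depth = 18, x = 30, diameter = 10),
       materials = tissue_materials(),
       protocol = indentation_protocol(positions = probe_positions(60, 5),
                                       depths = 2, increments = 4))
}

test_that("synthetic measurements are reproducible and honest about noise", {
  b <- tiny_bundle()
  mesh <- build_mesh(b$domain, b$nodule)
  clean <- synth_measurement(b, noise_model(), mesh = mesh)
  plain <- sweep_indent(mesh, b$materials, b$protocol)
  # zero noise: identical to the simulation, only retagged
  expect_identical(clean[[1]]$forces, plain[[1]]$forces)
  expect_equal(clean[[1]]$source, "synthetic")

  nm <- noise_model(sigma = 0.02, contact_offset = 0.2, seed = 42)
  m1 <- synth_measurement(b, nm, mesh = mesh)
  m2 <- synth_measurement(b, nm, mesh = mesh)
  expect_identical(m1[[1]]$forces, m2[[1]]$forces)    # same seed, same data
  m3 <- synth_measurement(b, noise_model(sigma = 0.02, contact_offset = 0.2,
                                         seed = 43), mesh = mesh)
  expect_false(identical(m1[[1]]$forces, m3[[1]]$forces))
})

test_that("force noise is zero-mean across seeds", {
  b <- tiny_bundle()
  mesh <- build_mesh(b$domain, b$nodule)
  clean <- sweep_indent(mesh, b$materials, b$protocol)[[1]]$forces
  acc <- matrix(0, 50, length(clean))
  for (s in 1:50)
    acc[s, ] <- synth_measurement(b, noise_model(sigma = 0.02, seed = s),
                                  mesh = mesh)[[1]]$forces
  expect_true(all(abs(colMeans(acc) - clean) / clean < 0.01))
})

test_that("noise model bounds are enforced", {
  expect_error(noise_model(contact_offset = 0.7), "0.5 mm")
  expect_error(noise_model(sigma = -0.1))
})
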