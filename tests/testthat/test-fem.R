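# FEM solver checks run on deliberately coarse meshes; physics properties
# (symmetry, scaling, monotonicity) hold at any resolution.

test_that("zero indentation depth gives zero force", {
  mesh <- build_mesh(quick_domain(), NULL)
  expect_equal(indent_once(mesh, tissue_materials(), 50, 0), 0)
})

test_that("forces are symmetric about the centreline of a homogeneous block", {
  mesh <- build_mesh(quick_domain(), NULL)
  f_l <- indent_once(mesh, tissue_materials(), 30, 4)
  f_r <- indent_once(mesh, tissue_materials(), 70, 4)
  expect_equal(f_l, f_r, tolerance = 0.005)
})

test_that("doubling all mu doubles the force (incompressible scaling)", {
  mats <- tissue_materials()
  mats2 <- list(healthy = ogden_from_modulus(mats$healthy, 20, 40),
                cancer = ogden_from_modulus(mats$cancer, 40, 80))
  mesh <- build_mesh(quick_domain(), NULL)
  f1 <- indent_once(mesh, mats, 50, 4)
  f2 <- indent_once(mesh, mats2, 50, 4)
  expect_equal(f2 / f1, 2, tolerance = 1e-3)
})

test_that("force increases monotonically and superlinearly with depth", {
  mesh <- build_mesh(quick_domain(), NULL)
  sol <- palpquant:::indent_solve(mesh, tissue_materials(), 50, 10,
                                  record_depths = c(1, 5, 10))
  f <- sol$recorded
  expect_true(f[2] > f[1] && f[3] > f[2])
  expect_true(all(diff(sol$force_hist) > 0))
  # spherical-tip contact: stiffness grows as contact widens
  expect_gt(f[3] - f[2], (f[2] - f[1]) * 5 / 4 / 4)
})

test_that("a recorded loading-path force equals a fresh solve at that depth", {
  mesh <- build_mesh(quick_domain(), NULL)
  sol <- palpquant:::indent_solve(mesh, tissue_materials(), 50, 10,
                                  record_depths = c(5, 10))
  fresh <- indent_once(mesh, tissue_materials(), 50, 5)
  expect_equal(sol$recorded[1], fresh, tolerance = 1e-6)
})

test_that("a stiff nodule under the probe increases the force at all depths", {
  dom <- quick_domain()
  mesh_n <- build_mesh(dom, nodule_spec("circle", depth = 30, x = 50,
                                        diameter = 20))
  mesh_h <- build_mesh(dom, NULL)
  sn <- palpquant:::indent_solve(mesh_n, tissue_materials(), 50, 10,
                                 record_depths = c(1, 5, 10))
  sh <- palpquant:::indent_solve(mesh_h, tissue_materials(), 50, 10,
                                 record_depths = c(1, 5, 10))
  expect_true(all(sn$recorded > sh$recorded))
})

# probe axis on a mesh node: the displacement mode's surface sampling and
# the penalty mode's true contact patch then resolve the same geometry
test_that("displacement and penalty contact agree within the mode budget", {
  mesh <- build_mesh(tissue_domain(100, 100, 5), NULL)
  fd <- indent_once(mesh, tissue_materials(), 50, 5, mode = "displacement")
  fp <- indent_once(mesh, tissue_materials(), 50, 5, mode = "penalty")
  expect_equal(fp / fd, 1, tolerance = 0.03)
})

test_that("penalty contact is frictionless: |Fx| under 1% of Fz", {
  mesh <- build_mesh(tissue_domain(100, 100, 5), NULL)
  sol <- indent_once(mesh, tissue_materials(), 50, 5, mode = "penalty",
                     details = TRUE)
  expect_lt(abs(sol$fx), 0.01 * sol$force)
})

test_that("external work matches stored energy for the quasi-static solve", {
  mesh <- build_mesh(quick_domain(), NULL)
  sol <- palpquant:::indent_solve(mesh, tissue_materials(), 50, 6,
                                  increments = 24)
  expect_equal(sol$work / sol$energy, 1, tolerance = 0.02)
})

test_that("halving the mesh size changes the peak force by less than 2%", {
  mats <- tissue_materials()
  f_coarse <- indent_once(build_mesh(tissue_domain(100, 100, 6), NULL),
                          mats, 50, 10)
  f_fine <- indent_once(build_mesh(tissue_domain(100, 100, 3), NULL),
                        mats, 50, 10)
  expect_equal(f_coarse / f_fine, 1, tolerance = 0.02)
})

test_that("protocol and position validation reject bad input", {
  expect_error(indentation_protocol(c(10, 5), 1), "ascending")
  expect_error(indentation_protocol(10, c(5, 1)), "ascending")
  expect_error(indentation_protocol(10, -1), "positive")
  mesh <- build_mesh(quick_domain(), NULL)
  expect_error(indent_once(mesh, tissue_materials(), 150, 2), "outside")
})
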