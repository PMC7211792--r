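# Shared fixtures.  All FEM problems here are deliberately small; the
# closed-loop cases below are computed once per test run and reused by the
# acceptance and property tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, fun) {
  if (!exists(name, envir = .fixture_env))
    assign(name, fun(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tissue_materials <- function()
  list(healthy = ogden_healthy_tissue(), cancer = ogden_cancerous_nodule())

# small homogeneous block + coarse protocol for fast FEM checks
quick_domain <- function() tissue_domain(100, 100, 8)

# random isochoric deformation states for material property loops
random_isochoric_states <- function(n, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    l1 <- exp(stats::runif(1, -0.3, 0.3))
    l2 <- exp(stats::runif(1, -0.3, 0.3))
    deformation_state(c(l1, l2, 1 / (l1 * l2)))
  })
}

# full closed-loop worked example: coarse circular-nodule library plus a
# synthetic measurement from the same forward model, inverted end to end
closed_loop_case <- function(diameter, depth, lib_depths, lib_diameters,
                             mesh_size = 6, n_positions = 13) {
  dom <- tissue_domain(100, 100, mesh_size)
  mats <- tissue_materials()
  prot <- indentation_protocol(positions = probe_positions(100, n_positions),
                               depths = c(1, 5, 10))
  lib <- build_library(dom, mats, prot, diameters = lib_diameters,
                       depths = lib_depths, smoothing = 0)
  bundle <- list(domain = dom,
                 nodule = nodule_spec("circle", depth = depth, x = 50,
                                      diameter = diameter),
                 materials = mats, protocol = prot)
  meas <- synth_measurement(bundle)
  base <- sweep_indent(build_mesh(dom, NULL), mats, prot)
  pos <- localize_nodule(meas[[3]], base[[3]])
  res <- suppressWarnings(quantify_profiles(lib, meas, pos, smoothing = 0))
  list(lib = lib, measurement = meas, baseline = base, localized = pos,
       result = res, bundle = bundle)
}

example1_loop <- function()
  memo("example1", function()
    closed_loop_case(diameter = 16, depth = 30,
                     lib_depths = c(30, 40, 50),
                     lib_diameters = c(10, 16, 22, 30)))

example2_loop <- function()
  memo("example2", function()
    closed_loop_case(diameter = 30, depth = 45,
                     lib_depths = c(35, 45, 55),
                     lib_diameters = c(16, 22, 30, 36)))
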