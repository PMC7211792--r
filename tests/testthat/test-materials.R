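test_that("Ogden energy vanishes in the reference state and is linear in mu", {
  ref <- deformation_state(c(1, 1, 1))
  expect_equal(ogden_energy(ref, ogden_healthy_tissue()), 0)
  expect_equal(ogden_energy(ref, ogden_cancerous_nodule()), 0)

  # cancerous mu_i are exactly double the healthy ones -> doubled energy
  st <- deformation_state(c(1.2, 1.2^-0.5, 1.2^-0.5))
  expect_equal(ogden_energy(st, ogden_cancerous_nodule()),
               2 * ogden_energy(st, ogden_healthy_tissue()))

  # general linearity over random states
  for (s in random_isochoric_states(10)) {
    m1 <- ogden_material(mu = c(0.013, -0.004), alpha = c(2.1, -1.3))
    m3 <- ogden_material(mu = 3 * m1$mu, alpha = m1$alpha)
    expect_equal(ogden_energy(s, m3), 3 * ogden_energy(s, m1))
  }
})

test_that("Ogden energy matches a hand-evaluated closed form", {
  # one-term material, lambda3 = 1: psi = (2 mu / a^2)(l^a + l^-a + 1 - 3)
  st <- deformation_state(c(1.1, 1 / 1.1, 1))
  mat <- ogden_material(mu = 0.01, alpha = 2)
  expected <- (2 * 0.01 / 4) * (1.1^2 + 1.1^-2 - 2)   # 1.8223e-4 MPa
  expect_equal(ogden_energy(st, mat), expected, tolerance = 1e-12)
  expect_equal(expected, 1.8223e-4, tolerance = 1e-4)
})

test_that("energies are invariant under permutation of principal stretches", {
  mats <- list(ogden_healthy_tissue(), ogden_material(0.012, 2))
  for (s in random_isochoric_states(6)) {
    perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2), c(1, 3, 2))
    for (m in mats) {
      vals <- vapply(perms, function(p)
        ogden_energy(deformation_state(s$stretches[p]), m), numeric(1))
      expect_equal(max(vals) - min(vals), 0, tolerance = 1e-15)
    }
  }
})

test_that("one-term Ogden with mu = 2*C1, alpha = 2 equals neo-Hookean", {
  c1 <- 4.6898e-3
  og <- ogden_material(mu = 2 * c1, alpha = 2)
  nh <- neo_hookean_material(c1)
  for (s in random_isochoric_states(12, seed = 11))
    expect_equal(ogden_energy(s, og), neo_hookean_energy(s, nh),
                 tolerance = 1e-14)
})

test_that("neo-Hookean energy follows C1*(I1bar - 3)", {
  expect_equal(neo_hookean_energy(deformation_state(c(1, 1, 1)),
                                  neo_hookean_material(0.01)), 0)
  st <- deformation_state(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  expect_equal(st$i1bar, 1.1^2 + 2 / 1.1)
  expect_equal(neo_hookean_energy(st, neo_hookean_material(0.01)),
               0.01 * (1.21 + 2 / 1.1 - 3), tolerance = 1e-12)
  # incompressible contract
  expect_error(neo_hookean_energy(deformation_state(c(1, 1, 1), jel = 1.1),
                                  neo_hookean_material(0.01)), "jel")
})

test_that("modulus rescaling scales mu linearly and leaves alpha fixed", {
  h <- ogden_healthy_tissue()
  c40 <- ogden_from_modulus(h, 20, 40)
  expect_equal(c40$mu, c(0.04238, -0.0224))
  expect_equal(c40$alpha, h$alpha)

  same <- ogden_from_modulus(h, 20, 20)
  expect_equal(same$mu, h$mu)

  m <- ogden_from_modulus(ogden_material(0.02, 2), 10, 30)
  expect_equal(m$mu, 0.06)
  expect_error(ogden_from_modulus(h, -1, 20), "positive")
})

test_that("E = 6*C1 reproduces the fitted gel moduli", {
  expect_equal(signif(young_from_c1(neo_hookean_material(4.6898e-3)), 3), 28.1)
  expect_equal(signif(young_from_c1(neo_hookean_material(6.5872e-3)), 3), 39.5)
  expect_equal(young_from_c1(neo_hookean_material(1 / 6000)), 1)
})

test_that("small-strain uniaxial tangent equals 3 * sum(mu)", {
  # incompressible uniaxial energy psi(l) with stretches (l, 1/sqrt(l), ...);
  # the small-strain Young's modulus is d2 psi / d l2 at l = 1
  for (mat in list(ogden_healthy_tissue(), ogden_cancerous_nodule())) {
    psi <- function(l)
      ogden_energy(deformation_state(c(l, 1 / sqrt(l), 1 / sqrt(l))), mat)
    h <- 1e-3
    E <- (psi(1 + h) - 2 * psi(1) + psi(1 - h)) / h^2
    expect_equal(E, 3 * sum(mat$mu), tolerance = 1e-3)
  }
})

test_that("material constructors enforce their invariants", {
  expect_error(ogden_material(mu = c(0.01), alpha = c(2, 3)), "length")
  expect_error(ogden_material(mu = 0.01, alpha = 0), "non-zero")
  expect_error(ogden_material(mu = c(-0.02, 0.01), alpha = c(2, 2)),
               "positive")
  expect_error(neo_hookean_material(-1), "positive")
  expect_error(deformation_state(c(1.5, 1, 1)), "isochoric")
  expect_error(deformation_state(c(1, -1, -1)), "positive")
  expect_error(ogden_energy(deformation_state(c(1, 1, 1), jel = 1.2),
                            ogden_healthy_tissue()), "jel")
})

# cheap forward oracle for the fitter: forces scale linearly in C1, which is
# the exact scaling of an incompressible neo-Hookean indentation response
linear_forward <- function(shape) {
  function(c1) lapply(seq_along(shape$depths), function(k)
    force_profile(shape$depths[k], shape$positions,
                  c1 * shape$gain[k, ], source = "simulated"))
}

fit_shape <- function() {
  positions <- seq(10, 90, by = 10)
  depths <- c(2, 4, 6)
  set.seed(3)
  gain <- outer(depths, seq_along(positions),
                function(d, i) d * (10 + 3 * sin(i)))
  list(positions = positions, depths = depths, gain = gain)
}

test_that("neo-Hookean fit recovers the generating constant exactly", {
  sh <- fit_shape()
  fwd <- linear_forward(sh)
  for (c1_true in c(1e-3, 5e-3, 2e-2)) {
    meas <- fwd(c1_true)
    fit <- fit_neo_hookean(meas, fwd, init_c1 = 8e-3)
    expect_equal(fit$material$c1, c1_true, tolerance = 1e-3)
    expect_lt(fit$max_error, 1e-6)
    expect_lte(fit$min_error, fit$mean_error)
    expect_lte(fit$mean_error, fit$max_error)
    expect_equal(fit$young_modulus_kpa, 6000 * fit$material$c1)
  }
})

test_that("duplicating every data point leaves the fit unchanged", {
  sh <- fit_shape()
  fwd <- linear_forward(sh)
  meas <- fwd(5e-3)
  fit1 <- fit_neo_hookean(meas, fwd, init_c1 = 1e-2)
  fwd2 <- function(c1) c(fwd(c1), fwd(c1))
  fit2 <- fit_neo_hookean(c(meas, meas), fwd2, init_c1 = 1e-2)
  expect_equal(fit2$material$c1, fit1$material$c1, tolerance = 1e-10)
})

test_that("fit is unbiased under zero-mean force noise", {
  sh <- fit_shape()
  fwd <- linear_forward(sh)
  clean <- fwd(5e-3)
  fmax <- max(unlist(lapply(clean, `[[`, "forces")))
  est <- vapply(1:50, function(seed) {
    set.seed(seed)
    noisy <- lapply(clean, function(p) {
      p$forces <- pmax(1e-9, p$forces + stats::rnorm(length(p$forces),
                                                     0, 0.02 * fmax))
      p
    })
    fit_neo_hookean(noisy, fwd, init_c1 = 1e-2)$material$c1
  }, numeric(1))
  expect_lt(abs(mean(est) - 5e-3) / 5e-3, 0.02)
})

test_that("fit rejects measurements containing zero forces", {
  sh <- fit_shape()
  fwd <- linear_forward(sh)
  meas <- fwd(5e-3)
  meas[[1]]$forces[1] <- 0
  expect_error(fit_neo_hookean(meas, fwd), "zero")
})
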