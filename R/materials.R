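#' Constitutive models for soft-tissue palpation simulation
#'
#' Containers and operations for the two hyperelastic material models used
#' throughout the package: a second-order Ogden model (principal-stretch form)
#' for prostate-like tissue and an incompressible neo-Hookean model for
#' gelatin phantom materials.  Units are fixed package-wide: lengths in mm,
#' forces in N (per mm out-of-plane thickness in 2D), stress-like moduli in
#' MPa.
#'
#' @name materials
NULL

#' Ogden hyperelastic material
#'
#' Second-order (or general order) Ogden strain-energy density in principal
#' stretches,
#' \deqn{\Psi = \sum_i \frac{2\mu_i}{\alpha_i^2}
#'   (\bar\lambda_1^{\alpha_i} + \bar\lambda_2^{\alpha_i} +
#'    \bar\lambda_3^{\alpha_i} - 3) + \sum_i \frac{1}{D_i}(J_{el}-1)^{2i}.}
#' The volumetric sum is omitted when `d` is empty (fully incompressible
#' treatment).  The initial shear modulus is \eqn{\mu_0 = \sum_i \mu_i} and
#' the equivalent small-strain Young's modulus (incompressible) is
#' \eqn{E = 3\mu_0}.
#'
#' @param mu numeric vector of stress-like coefficients \eqn{\mu_i} (MPa).
#' @param alpha numeric vector of dimensionless exponents \eqn{\alpha_i}.
#' @param d optional numeric vector of volumetric compliances \eqn{D_i}
#'   (1/MPa); empty for an incompressible material.
#' @return An object of class `ogden_material`.
#' @examples
#' ogden_material(mu = c(0.02119, -0.0112), alpha = c(2.244, -1.081))
#' @export
ogden_material <- function(mu, alpha, d = numeric(0)) {
  stopifnot(is.numeric(mu), is.numeric(alpha), is.numeric(d))
  if (length(mu) != length(alpha))
    stop("mu and alpha must have the same length (the model order)")
  if (length(d) && length(d) != length(mu))
    stop("d must be empty or of the same length as mu")
  if (any(alpha == 0)) stop("all alpha_i must be non-zero")
  if (sum(mu) <= 0)
    stop("initial shear modulus sum(mu) must be positive for stability")
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 d = as.numeric(d), order = length(mu)),
            class = "ogden_material")
}

#' Incompressible neo-Hookean material
#'
#' One-parameter model \eqn{\Psi = C_1(\bar I - 3)} with \eqn{\bar I} the
#' first isochoric invariant of the left Cauchy-Green tensor.  For an
#' incompressible material \eqn{E = 6 C_1}.
#'
#' @param c1 material constant \eqn{C_1} in MPa.
#' @return An object of class `neo_hookean_material`.
#' @export
neo_hookean_material <- function(c1) {
  stopifnot(is.numeric(c1), length(c1) == 1)
  if (c1 <= 0) stop("c1 must be positive")
  structure(list(c1 = as.numeric(c1)), class = "neo_hookean_material")
}

#' Isochoric deformation state in principal stretches
#'
#' @param stretches isochoric principal stretches
#'   \eqn{(\bar\lambda_1,\bar\lambda_2,\bar\lambda_3)}; their product must
#'   equal 1.
#' @param jel elastic volume ratio \eqn{J_{el}} (1 for incompressible).
#' @return An object of class `deformation_state` with fields
#'   `stretches`, `jel` and the first isochoric invariant `i1bar`.
#' @export
deformation_state <- function(stretches, jel = 1) {
  stopifnot(length(stretches) == 3, is.numeric(stretches))
  if (any(stretches <= 0)) stop("principal stretches must be positive")
  if (abs(prod(stretches) - 1) > 1e-8)
    stop("isochoric stretches must satisfy lambda1*lambda2*lambda3 == 1")
  if (jel <= 0) stop("jel must be positive")
  i1bar <- sum(stretches^2)
  structure(list(stretches = as.numeric(stretches), jel = as.numeric(jel),
                 i1bar = i1bar),
            class = "deformation_state")
}

#' Ogden strain-energy density
#'
#' Evaluates the Ogden energy at an isochoric deformation state.  When the
#' material carries no volumetric compliances (`d` empty) the state must be
#' fully incompressible (`jel == 1`).
#'
#' @param state a [deformation_state()].
#' @param mat an [ogden_material()].
#' @return Energy density in MPa.
#' @export
ogden_energy <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"), inherits(mat, "ogden_material"))
  if (!length(mat$d) && abs(state$jel - 1) > 1e-12)
    stop("incompressible material: jel must equal 1")
  lb <- state$stretches
  dev <- sum(2 * mat$mu / mat$alpha^2 *
               (lb[1]^mat$alpha + lb[2]^mat$alpha + lb[3]^mat$alpha - 3))
  vol <- 0
  if (length(mat$d)) {
    i <- seq_along(mat$d)
    nz <- mat$d != 0
    vol <- sum((1 / mat$d[nz]) * (state$jel - 1)^(2 * i[nz]))
  }
  dev + vol
}

#' Neo-Hookean strain-energy density
#'
#' @param state a [deformation_state()]; must be isochoric (`jel == 1`).
#' @param mat a [neo_hookean_material()].
#' @return Energy density \eqn{C_1(\bar I - 3)} in MPa.
#' @export
neo_hookean_energy <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(mat, "neo_hookean_material"))
  if (abs(state$jel - 1) > 1e-12)
    stop("incompressible model: jel must equal 1")
  mat$c1 * (state$i1bar - 3)
}

#' Rescale an Ogden material to a different equivalent Young's modulus
#'
#' The Ogden energy is linear in the \eqn{\mu_i}, so a material with a
#' different small-strain modulus is obtained by scaling every \eqn{\mu_i} by
#' the modulus ratio (exponents unchanged, volumetric compliances scaled
#' inversely).  This is how the stiff-nodule parameters relate to the healthy
#' ones for a 2:1 modulus ratio.
#'
#' @param reference an [ogden_material()].
#' @param e_ref_kpa equivalent Young's modulus of `reference` (kPa).
#' @param e_target_kpa target equivalent Young's modulus (kPa).
#' @return A new [ogden_material()].
#' @export
ogden_from_modulus <- function(reference, e_ref_kpa, e_target_kpa) {
  stopifnot(inherits(reference, "ogden_material"))
  if (e_ref_kpa <= 0 || e_target_kpa <= 0) stop("moduli must be positive")
  s <- e_target_kpa / e_ref_kpa
  ogden_material(mu = reference$mu * s, alpha = reference$alpha,
                 d = if (length(reference$d)) reference$d / s else numeric(0))
}

#' Young's modulus implied by a neo-Hookean constant
#'
#' Incompressible relation \eqn{E = 6 C_1}; with \eqn{C_1} in MPa the result
#' is \eqn{E_{kPa} = 6000\, C_1}.
#'
#' @param mat a [neo_hookean_material()] (c1 in MPa).
#' @return Young's modulus in kPa.
#' @export
young_from_c1 <- function(mat) {
  stopifnot(inherits(mat, "neo_hookean_material"))
  6000 * mat$c1
}

#' Reference Ogden parameters for prostate-like tissue
#'
#' Second-order Ogden parameters fitted to prostate-mimicking tissue with an
#' equivalent Young's modulus of 20 kPa (healthy) and, via [ogden_from_modulus()]
#' with exactly doubled \eqn{\mu_i}, 40 kPa (cancerous nodule).  Both are
#' treated as fully incompressible.
#'
#' @return An [ogden_material()].
#' @export
ogden_healthy_tissue <- function() {
  ogden_material(mu = c(0.02119, -0.01120), alpha = c(2.244, -1.081))
}

#' @rdname ogden_healthy_tissue
#' @export
ogden_cancerous_nodule <- function() {
  ogden_from_modulus(ogden_healthy_tissue(), 20, 40)
}

#' Internal: material parameter row for the FEM kernel
#'
#' Maps a constitutive model to the (mu1, alpha1, mu2, alpha2, kappa) row the
#' element kernel consumes.  A neo-Hookean material is the exact one-term
#' Ogden material with mu = 2*C1, alpha = 2.  The penalty bulk modulus
#' defaults to `penalty_factor` times the initial shear modulus.
#'
#' @noRd
fem_material_row <- function(mat, penalty_factor = 200) {
  if (inherits(mat, "neo_hookean_material"))
    mat <- ogden_material(mu = 2 * mat$c1, alpha = 2)
  stopifnot(inherits(mat, "ogden_material"))
  mu0 <- sum(mat$mu)
  mu <- mat$mu
  al <- mat$alpha
  if (length(mu) == 1) { mu <- c(mu, 0); al <- c(al, 2) }
  if (length(mu) != 2) stop("FEM kernel supports one- or two-term Ogden models")
  c(mu[1], al[1], mu[2], al[2], penalty_factor * mu0)
}

#' Fit a neo-Hookean constant to indentation force data
#'
#' Identifies \eqn{C_1} by minimizing the sum of squared force residuals
#' \eqn{\sum_{depth}\sum_{pos} (F_{sim}(C_1) - F_{meas})^2} over all
#' indentation depths and positions, using damped (Levenberg-Marquardt)
#' nonlinear least squares.
#'
#' @param measured list of [force_profile()] objects (the measurement).
#' @param forward function mapping a scalar `c1` (MPa) to a list of force
#'   profiles over exactly the same depths and positions as `measured`.
#' @param init_c1 starting value for \eqn{C_1} (MPa).
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param tol relative parameter-change convergence tolerance.
#' @return A `fit_result` list with the fitted [neo_hookean_material()],
#'   per-point relative errors, their max/min/mean, and the implied
#'   Young's modulus in kPa.
#' @export
fit_neo_hookean <- function(measured, forward, init_c1 = 5e-3,
                            max_iter = 200, tol = 1e-8) {
  stopifnot(is.list(measured), length(measured) >= 1, is.function(forward))
  f_exp <- unlist(lapply(measured, function(p) p$forces))
  if (any(f_exp == 0))
    stop("measured forces contain zeros; relative error is undefined")
  residfun <- function(par) {
    sim <- forward(par[1])
    unlist(lapply(sim, function(p) p$forces)) - f_exp
  }
  fit <- minpack.lm::nls.lm(
    par = init_c1, fn = residfun,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = tol,
                                         ftol = tol))
  if (fit$info == 0 || fit$info == 5)
    stop("Levenberg-Marquardt did not converge; residual trace: ",
         paste(signif(fit$rsstrace, 6), collapse = ", "))
  c1 <- as.numeric(fit$par)
  mat <- neo_hookean_material(c1)
  f_fit <- unlist(lapply(forward(c1), function(p) p$forces))
  per_point <- abs(f_fit - f_exp) / abs(f_exp)
  structure(list(material = mat,
                 per_point_error = per_point,
                 max_error = max(per_point),
                 min_error = min(per_point),
                 mean_error = mean(per_point),
                 young_modulus_kpa = young_from_c1(mat),
                 rss_trace = fit$rsstrace,
                 iterations = fit$niter),
            class = "fit_result")
}
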