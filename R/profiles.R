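#' Force-feedback profile
#'
#' One palpation sweep: the vertical reaction force at each probed surface
#' position, at a single indentation depth.
#'
#' @param indentation_depth indentation depth U (mm).
#' @param positions probed surface x-coordinates (mm), strictly ascending.
#' @param forces reaction forces (N per mm out-of-plane thickness), `>= 0`.
#' @param source one of `"simulated"`, `"measured"`, `"synthetic"`.
#' @return An object of class `force_profile`.
#' @export
force_profile <- function(indentation_depth, positions, forces,
                          source = c("simulated", "measured", "synthetic")) {
  source <- match.arg(source)
  stopifnot(is.numeric(positions), is.numeric(forces),
            length(positions) == length(forces))
  if (indentation_depth < 0) stop("indentation_depth must be non-negative")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly ascending")
  if (any(forces < 0)) stop("forces must be non-negative")
  structure(list(indentation_depth = indentation_depth,
                 positions = as.numeric(positions),
                 forces = as.numeric(forces), source = source),
            class = "force_profile")
}

#' Localize a nodule from a force profile
#'
#' Finds the surface position where the force feedback differs most from the
#' healthy-background baseline.  If the maximal difference does not exceed a
#' noise floor, no nodule is detected and `NA` is returned.
#'
#' @param profile a [force_profile()] over the suspect tissue.
#' @param baseline a [force_profile()] from the homogeneous (healthy)
#'   background at the same positions and indentation depth.
#' @param noise_floor detection threshold on `max |F - F_baseline|`; by
#'   default 3 times the baseline's residual spread about a GCV smoothing
#'   spline (zero for noiseless simulated data), propagated to the
#'   difference profile.  Ties are broken toward the centre of the probed
#'   line.
#' @return The nodule position (mm), or `NA_real_` when no nodule is
#'   detected (with the maximal difference in attribute `"max_diff"`).
#' @export
localize_nodule <- function(profile, baseline, noise_floor = NULL) {
  stopifnot(inherits(profile, "force_profile"),
            inherits(baseline, "force_profile"))
  if (length(profile$positions) != length(baseline$positions) ||
      any(abs(profile$positions - baseline$positions) > 1e-9))
    stop("profile and baseline must share probe positions")
  if (abs(profile$indentation_depth - baseline$indentation_depth) > 1e-9)
    stop("profile and baseline must share the indentation depth")
  dF <- profile$forces - baseline$forces
  if (is.null(noise_floor)) {
    # measurement-noise scale of the baseline: residual spread about a GCV
    # smoothing spline.  A noiseless baseline is interpolated (zero floor);
    # short profiles (n < 8), where GCV degenerates, use a
    # near-interpolating fit instead
    n <- length(baseline$positions)
    sigma <- 0
    if (n >= 4) {
      fit <- tryCatch(
        if (n >= 8)
          stats::smooth.spline(baseline$positions, baseline$forces,
                               cv = FALSE, keep.data = FALSE)
        else
          stats::smooth.spline(baseline$positions, baseline$forces,
                               df = n, keep.data = FALSE),
        error = function(e) NULL)
      if (!is.null(fit))
        sigma <- stats::sd(baseline$forces -
                             stats::predict(fit, baseline$positions)$y)
    }
    noise_floor <- 3 * sqrt(2) * sigma
  }
  adF <- abs(dF)
  m <- max(adF)
  if (!(m > noise_floor)) {
    out <- NA_real_
    attr(out, "max_diff") <- m
    return(out)
  }
  cand <- which(adF >= m * (1 - 1e-12))
  centre <- mean(range(profile$positions))
  pos <- profile$positions[cand]
  pos[which.min(abs(pos - centre))]
}

# spline fit shared by second_derivative and curvature_profile
fit_force_spline <- function(profile, smoothing) {
  x <- profile$positions
  y <- profile$forces
  if (length(x) < 5)
    stop("at least 5 data points are required for the spline fit")
  if (identical(smoothing, "auto")) {
    # automatic smoothness by REML (mgcv): markedly more stable for
    # derivative estimation than smooth.spline's GCV, whose occasional
    # undersmoothing makes curvature estimates heavy-tailed.  The second
    # derivative is evaluated by central differencing of the fitted spline
    # at a step far below the knot spacing (exact for a cubic piece).
    k <- max(3, min(20, length(x) - 1))
    dat <- data.frame(.x = x, .y = y)
    fit <- mgcv::gam(.y ~ s(.x, bs = "cr", k = k), data = dat,
                     method = "REML")
    rng <- range(x)
    h <- diff(rng) / 400
    list(predict2 = function(at) {
      a <- pmin(pmax(at, rng[1] + h), rng[2] - h)
      p <- function(z) as.numeric(stats::predict(fit,
                                                 newdata = data.frame(.x = z)))
      (p(a + h) - 2 * p(a) + p(a - h)) / h^2
    }, smoothing = "REML")
  } else {
    stopifnot(is.numeric(smoothing), length(smoothing) == 1, smoothing >= 0)
    if (smoothing == 0) {
      f <- stats::splinefun(x, y, method = "fmm")
      list(predict2 = function(at) f(at, deriv = 2), smoothing = 0)
    } else {
      fit <- stats::smooth.spline(x, y, lambda = smoothing, keep.data = FALSE)
      list(predict2 = function(at) stats::predict(fit, at, deriv = 2)$y,
           smoothing = fit$lambda)
    }
  }
}

#' Second derivative of a force profile
#'
#' Fits a cubic spline to the whole force-vs-position profile and returns its
#' analytic second derivative at the requested position.  With
#' `smoothing = "auto"` a smoothing spline is used and the smoothing
#' parameter chosen by generalized cross-validation; `smoothing = 0` uses an
#' exact interpolating cubic spline (which reproduces polynomials up to
#' cubic order exactly); a positive number is used directly as the smoothing
#' spline's `lambda` (on the standardized position scale of
#' [stats::smooth.spline()]).
#'
#' @param profile a [force_profile()] with at least 5 points.
#' @param at position (mm) at which to evaluate; must lie within the probed
#'   range (no extrapolation).
#' @param smoothing `"auto"`, `0`, or a positive smoothing parameter.
#' @return Second derivative of force with respect to position
#'   (N/mm^3 per unit thickness), with the smoothing parameter used in
#'   attribute `"smoothing"`.
#' @export
second_derivative <- function(profile, at, smoothing = "auto") {
  stopifnot(inherits(profile, "force_profile"), is.numeric(at),
            length(at) == 1)
  rng <- range(profile$positions)
  if (at < rng[1] || at > rng[2])
    stop("evaluation position outside the probed range (no extrapolation)")
  fit <- fit_force_spline(profile, smoothing)
  out <- fit$predict2(at)
  attr(out, "smoothing") <- fit$smoothing
  out
}

#' Curvature profile of a force sweep
#'
#' Second derivative of the spline fit evaluated at every probed position.
#' Positions within one indenter radius of the domain edges are flagged
#' unreliable (boundary effects of both the sweep and the spline) and should
#' be excluded from inversion.
#'
#' @inheritParams second_derivative
#' @param indenter_radius radius (mm) used for the edge-reliability flag.
#' @return An object of class `curvature_profile` with fields
#'   `indentation_depth`, `positions`, `second_derivative`, `smoothing`,
#'   `reliable`.
#' @export
curvature_profile <- function(profile, smoothing = "auto",
                              indenter_radius = 5) {
  stopifnot(inherits(profile, "force_profile"))
  fit <- fit_force_spline(profile, smoothing)
  d2 <- fit$predict2(profile$positions)
  rng <- range(profile$positions)
  reliable <- profile$positions >= rng[1] + indenter_radius &
    profile$positions <= rng[2] - indenter_radius
  structure(list(indentation_depth = profile$indentation_depth,
                 positions = profile$positions,
                 second_derivative = d2,
                 smoothing = fit$smoothing,
                 reliable = reliable),
            class = "curvature_profile")
}
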