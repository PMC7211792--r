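#' Calibration library over nodule depth, diameter and indentation depth
#'
#' The inversion works by comparing a measured force-profile second
#' derivative against a precomputed library: for every combination of
#' (nodule depth, nodule diameter, indentation depth) a forward simulation
#' of a circular nodule centred under the probed line's midpoint is run and
#' the spline second derivative at the nodule position is stored.  Along the
#' diameter axis the stored values are monotone in magnitude, which is what
#' makes the inversion well defined per depth.
#'
#' @param domain a [tissue_domain()].
#' @param materials material list as in [indent_once()].
#' @param protocol an [indentation_protocol()]; its `depths` become the
#'   library's indentation depths.
#' @param diameters ascending grid of nodule diameters (mm).
#' @param depths ascending grid of nodule centre depths (mm).
#' @param smoothing spline smoothing passed to [second_derivative()]; must
#'   match the setting used on the measurement.
#' @param verbose print progress.
#' @param ... passed to [sweep_indent()].
#' @return An object of class `calibration_library`: grids, a 3D value
#'   array `[depth, diameter, indentation depth]` and provenance metadata.
#' @export
build_library <- function(domain, materials, protocol, diameters, depths,
                          smoothing = "auto", verbose = FALSE, ...) {
  stopifnot(inherits(domain, "tissue_domain"),
            inherits(protocol, "indentation_protocol"),
            length(diameters) >= 1, length(depths) >= 1)
  if (is.unsorted(diameters, strictly = TRUE) ||
      is.unsorted(depths, strictly = TRUE))
    stop("diameter and depth grids must be strictly ascending")
  centre <- mean(range(protocol$positions))
  bad <- list()
  for (de in depths) for (di in diameters) {
    if (de - di / 2 <= 0 || de + di / 2 >= domain$height ||
        centre - di / 2 <= 0 || centre + di / 2 >= domain$width)
      bad[[length(bad) + 1]] <- c(de, di)
  }
  if (length(bad))
    stop("geometrically infeasible (depth, diameter) combinations: ",
         paste(vapply(bad, function(b) sprintf("(%g, %g)", b[1], b[2]), ""),
               collapse = ", "))
  vals <- array(NA_real_,
                dim = c(length(depths), length(diameters),
                        length(protocol$depths)),
                dimnames = list(depth = depths, diameter = diameters,
                                indentation = protocol$depths))
  for (i in seq_along(depths)) for (j in seq_along(diameters)) {
    nod <- nodule_spec("circle", depth = depths[i], x = centre,
                       diameter = diameters[j])
    mesh <- build_mesh(domain, nod)
    profs <- sweep_indent(mesh, materials, protocol, ...)
    for (k in seq_along(profs))
      vals[i, j, k] <- as.numeric(
        second_derivative(profs[[k]], at = centre, smoothing = smoothing))
    if (verbose)
      message(sprintf("library: depth %g mm, diameter %g mm done",
                      depths[i], diameters[j]))
  }
  structure(list(diameters = as.numeric(diameters),
                 depths = as.numeric(depths),
                 indentation_depths = protocol$depths,
                 values = vals,
                 provenance = list(
                   width = domain$width, height = domain$height,
                   mesh_size = domain$mesh_size,
                   positions = protocol$positions,
                   indenter_radius = protocol$indenter_radius,
                   increments = protocol$increments,
                   smoothing = smoothing,
                   material_hash = provenance_hash(materials),
                   schema_version = 1L)),
            class = "calibration_library")
}

provenance_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Invert a measured second derivative into a depth-diameter curve
#'
#' For one indentation depth, finds at every tabulated nodule depth the
#' diameter whose library value equals the measured second derivative, by
#' shape-preserving monotone interpolation along the diameter axis.  Depths
#' at which the measured value falls outside the library's range are
#' omitted; if it is out of range at every depth the curve is empty (the
#' nodule is outside the calibrated envelope).
#'
#' @param lib a [build_library()] result.
#' @param measured_d2 measured second derivative (N/mm^3 per unit thickness).
#' @param indentation_depth which library indentation depth (mm) the
#'   measurement was taken at.
#' @return An object of class `depth_diameter_curve` with fields
#'   `indentation_depth`, `depths`, `diameters` (points sorted by depth).
#' @export
invert_to_curve <- function(lib, measured_d2, indentation_depth) {
  stopifnot(inherits(lib, "calibration_library"))
  k <- which(abs(lib$indentation_depths - indentation_depth) < 1e-9)
  if (length(k) != 1)
    stop("indentation depth ", indentation_depth, " not in the library")
  dd <- numeric(0); dia <- numeric(0)
  for (i in seq_along(lib$depths)) {
    v <- lib$values[i, , k]
    if (length(v) == 1) {
      if (abs(measured_d2 - v) < 1e-12) {
        dd <- c(dd, lib$depths[i]); dia <- c(dia, lib$diameters[1])
      }
      next
    }
    s <- sign(diff(v))
    if (any(s == 0) || length(unique(s)) != 1) {
      warning(sprintf(
        "library values not strictly monotone in diameter at depth %g mm; skipped",
        lib$depths[i]))
      next
    }
    ord <- order(v)
    vs <- v[ord]; ds <- lib$diameters[ord]
    if (measured_d2 < vs[1] || measured_d2 > vs[length(vs)]) next
    f <- if (length(vs) >= 3)
      stats::splinefun(vs, ds, method = "monoH.FC") else
      function(x) stats::approx(vs, ds, xout = x)$y
    dd <- c(dd, lib$depths[i])
    dia <- c(dia, f(measured_d2))
  }
  structure(list(indentation_depth = indentation_depth,
                 depths = dd, diameters = dia,
                 empty = length(dd) == 0L),
            class = "depth_diameter_curve")
}

# squared distance from points (matrix p, normalized coords) to a polyline
polyline_dist2 <- function(px, py, vx, vy) {
  n <- length(vx)
  best <- (px - vx[1])^2 + (py - vy[1])^2
  if (n == 1) return(best)
  for (s in 1:(n - 1)) {
    ax <- vx[s]; ay <- vy[s]
    bx <- vx[s + 1] - ax; by <- vy[s + 1] - ay
    L2 <- bx^2 + by^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * bx + (py - ay) * by) / L2)) else 0
    d2 <- (px - (ax + t * bx))^2 + (py - (ay + t * by))^2
    best <- pmin(best, d2)
  }
  best
}

#' Intersect depth-diameter curves to quantify the nodule
#'
#' Each indentation depth contributes one depth-diameter curve; the nodule's
#' true parameters are where the curves meet.  When the curves do not share
#' an exact common point (noise, off-grid truth) the closest-approach
#' solution is returned: the point minimizing the sum of squared distances
#' to all curves in span-normalized coordinates (depth and diameter each
#' divided by the range covered by the curves, so the two axes contribute
#' comparably).  All local minima found are ranked by residual and reported
#' as candidates.
#'
#' @param curves list of at least two non-empty
#'   [depth_diameter_curve][invert_to_curve()] objects.
#' @param residual_ceiling reject the result (error) when even the best
#'   candidate's residual exceeds this (normalized squared distance).
#' @param ngrid resolution of the initial search grid.
#' @return An object of class `quantification_result` with `chosen`
#'   (named vector: depth, diameter), `residual`, `candidates` (data frame
#'   ranked by residual), `equivalent_radius` (mm, the recovered circle's
#'   radius) and `area` (mm^2).
#' @export
intersect_curves <- function(curves, residual_ceiling = 0.5, ngrid = 101) {
  stopifnot(is.list(curves), length(curves) >= 2)
  for (cv in curves) {
    stopifnot(inherits(cv, "depth_diameter_curve"))
    if (cv$empty)
      stop("empty depth-diameter curve at indentation depth ",
           cv$indentation_depth, " mm (nodule outside calibrated envelope)")
  }
  alld <- unlist(lapply(curves, `[[`, "depths"))
  alls <- unlist(lapply(curves, `[[`, "diameters"))
  # span floor of 1 mm: spans far below the library grid spacing would
  # otherwise inflate numerical noise into order-one normalized distances
  dspan <- max(diff(range(alld)), 1)
  sspan <- max(diff(range(alls)), 1)
  d0 <- min(alld); s0 <- min(alls)
  norm_curves <- lapply(curves, function(cv) {
    o <- order(cv$depths)
    list(vx = (cv$depths[o] - d0) / dspan, vy = (cv$diameters[o] - s0) / sspan)
  })
  obj <- function(p) {
    sum(vapply(norm_curves,
               function(nc) polyline_dist2(p[1], p[2], nc$vx, nc$vy),
               numeric(1)))
  }
  gx <- seq(0, 1, length.out = ngrid)
  gy <- seq(0, 1, length.out = ngrid)
  PX <- rep(gx, times = ngrid)
  PY <- rep(gy, each = ngrid)
  Gv <- numeric(length(PX))
  for (nc in norm_curves) Gv <- Gv + polyline_dist2(PX, PY, nc$vx, nc$vy)
  G <- matrix(Gv, ngrid, ngrid)
  # local minima on the grid (including the global one)
  is_min <- matrix(TRUE, ngrid, ngrid)
  shift <- function(M, di, dj) {
    out <- matrix(Inf, ngrid, ngrid)
    ri <- seq_len(ngrid) + di; rj <- seq_len(ngrid) + dj
    ok_i <- ri >= 1 & ri <= ngrid; ok_j <- rj >= 1 & rj <= ngrid
    out[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    out
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_min <- is_min & (G <= shift(G, di, dj))
  }
  idx <- which(is_min, arr.ind = TRUE)
  idx <- idx[order(G[idx]), , drop = FALSE]
  idx <- idx[seq_len(min(6, nrow(idx))), , drop = FALSE]
  cands <- NULL
  for (r in seq_len(nrow(idx))) {
    p0 <- c(gx[idx[r, 1]], gy[idx[r, 2]])
    op <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 500))
    cands <- rbind(cands, c(op$par, op$value))
  }
  # dedupe refined candidates
  keep <- rep(TRUE, nrow(cands))
  if (nrow(cands) > 1)
    for (r in 2:nrow(cands))
      for (q in 1:(r - 1))
        if (keep[q] && sum((cands[r, 1:2] - cands[q, 1:2])^2) < 1e-6)
          keep[r] <- FALSE
  cands <- cands[keep, , drop = FALSE]
  cands <- cands[order(cands[, 3]), , drop = FALSE]
  if (cands[1, 3] > residual_ceiling)
    stop(sprintf(
      "inconsistent measurements: best residual %.3g exceeds ceiling %.3g",
      cands[1, 3], residual_ceiling))
  out_df <- data.frame(depth = d0 + cands[, 1] * dspan,
                       diameter = s0 + cands[, 2] * sspan,
                       residual = cands[, 3])
  chosen <- c(depth = out_df$depth[1], diameter = out_df$diameter[1])
  structure(list(candidates = out_df,
                 chosen = chosen,
                 residual = out_df$residual[1],
                 equivalent_radius = unname(chosen["diameter"]) / 2,
                 area = pi * (unname(chosen["diameter"]) / 2)^2),
            class = "quantification_result")
}

#' Quantify a nodule from measured profiles and a calibration library
#'
#' Convenience composition of the inversion chain: extract the spline second
#' derivative of every measured profile at the nodule position, invert each
#' against the library, and intersect the resulting depth-diameter curves.
#' Indentation depths whose measurement falls outside the calibrated
#' envelope (empty curves — typically deep nodules probed too shallowly to
#' carry a resolvable signal) are dropped with a warning; at least two
#' usable curves are required.
#'
#' @param lib a [build_library()] result.
#' @param measured list of [force_profile()]s, one per indentation depth in
#'   the library.
#' @param position nodule position (mm), e.g. from [localize_nodule()].
#' @param smoothing spline smoothing; defaults to the setting the library
#'   was built with.
#' @return A [quantification_result][intersect_curves()].
#' @export
quantify_profiles <- function(lib, measured, position, smoothing = NULL) {
  stopifnot(inherits(lib, "calibration_library"), is.list(measured))
  if (is.null(smoothing)) {
    smoothing <- lib$provenance$smoothing
    if (is.null(smoothing)) smoothing <- "auto"
  }
  curves <- lapply(measured, function(p)
    invert_to_curve(lib, as.numeric(second_derivative(p, at = position,
                                                      smoothing = smoothing)),
                    p$indentation_depth))
  empty <- vapply(curves, `[[`, logical(1), "empty")
  if (any(empty)) {
    dropped <- vapply(curves[empty], `[[`, numeric(1), "indentation_depth")
    warning("measurement outside the calibrated envelope at indentation ",
            "depth(s) ", paste(dropped, collapse = ", "),
            " mm; dropped from the intersection")
  }
  kept <- curves[!empty]
  if (length(kept) < 2)
    stop("fewer than two usable depth-diameter curves; ",
         "extend the calibration library")
  intersect_curves(kept)
}

#' Equivalent radius of an irregular nodule
#'
#' Radius of the sphere with the same volume,
#' \eqn{R = (3 V / 4\pi)^{1/3}}, or (2D variant) of the circle with the same
#' area, \eqn{R = (A/\pi)^{1/2}}.
#'
#' @param volume nodule volume (mm^3).
#' @return Radius in mm.
#' @export
equivalent_radius <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' @rdname equivalent_radius
#' @param area nodule cross-sectional area (mm^2).
#' @export
equivalent_radius_2d <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  sqrt(area / pi)
}

#' Quantification errors against a known ground truth
#'
#' Relative errors, each `|predicted - true| / true * 100` (percent), of the
#' recovered nodule size (diameter / equivalent radius), depth, and area.
#'
#' @param result a [quantification_result][intersect_curves()].
#' @param truth a [nodule_spec()] (any shape; its area and centre depth are
#'   used), or a list with `depth` and either `diameter` or `area`.
#' @return Named vector `c(size_pct, depth_pct, area_pct)`.
#' @export
quantification_errors <- function(result, truth) {
  stopifnot(inherits(result, "quantification_result"))
  if (inherits(truth, "nodule_spec")) {
    true_depth <- nodule_center_y(truth)
    true_area <- nodule_area(truth)
    true_diam <- 2 * equivalent_radius_2d(true_area)
  } else {
    true_depth <- truth$depth
    if (!is.null(truth$diameter)) {
      true_diam <- truth$diameter
      true_area <- pi * (true_diam / 2)^2
    } else {
      true_area <- truth$area
      true_diam <- 2 * equivalent_radius_2d(true_area)
    }
  }
  if (any(c(true_depth, true_diam, true_area) == 0))
    stop("true values must be non-zero")
  c(size_pct = abs(result$chosen[["diameter"]] - true_diam) / true_diam * 100,
    depth_pct = abs(result$chosen[["depth"]] - true_depth) / true_depth * 100,
    area_pct = abs(result$area - true_area) / true_area * 100)
}

#' Maximum-force envelope over nodule depth and size at one indentation depth
#'
#' Demonstrates the depth-size ambiguity of single-depth palpation: for each
#' (nodule depth, diameter) combination the maximum force feedback over the
#' probed positions is computed; distinct combinations whose maxima differ
#' by less than `near_tol` are reported as indistinguishable at this
#' indentation depth.
#'
#' @param domain a [tissue_domain()].
#' @param materials material list as in [indent_once()].
#' @param indentation_depth single indentation depth (mm).
#' @param depth_grid nodule centre depths (mm).
#' @param size_grid nodule diameters (mm); a size of 0 means a homogeneous
#'   block.
#' @param positions probe positions (defaults to 7 sites around the centre).
#' @param near_tol relative force difference below which two combinations
#'   are reported as ambiguous (default 1%).
#' @param ... passed to [sweep_indent()].
#' @return An object of class `ambiguity_envelope`: `table` (data frame
#'   depth, size, max_force) and `near_pairs` (data frame of ambiguous
#'   pairs with their relative force difference).
#' @export
ambiguity_envelope <- function(domain, materials, indentation_depth,
                               depth_grid, size_grid, positions = NULL,
                               near_tol = 0.01, ...) {
  stopifnot(inherits(domain, "tissue_domain"), length(indentation_depth) == 1)
  centre <- domain$width / 2
  if (is.null(positions))
    positions <- centre + seq(-15, 15, length.out = 7)
  protocol <- indentation_protocol(positions = positions,
                                   depths = indentation_depth)
  combos <- expand.grid(depth = depth_grid, size = size_grid)
  mf <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    nod <- if (combos$size[r] == 0) NULL else
      nodule_spec("circle", depth = combos$depth[r], x = centre,
                  diameter = combos$size[r])
    mesh <- build_mesh(domain, nod)
    prof <- sweep_indent(mesh, materials, protocol, ...)[[1]]
    mf[r] <- max(prof$forces)
  }
  tab <- cbind(combos, max_force = mf)
  near <- NULL
  for (a in seq_len(nrow(tab) - 1)) for (b in (a + 1):nrow(tab)) {
    if (tab$depth[a] == tab$depth[b] && tab$size[a] == tab$size[b]) next
    rel <- abs(tab$max_force[a] - tab$max_force[b]) /
      mean(c(tab$max_force[a], tab$max_force[b]))
    if (rel < near_tol)
      near <- rbind(near, data.frame(
        depth1 = tab$depth[a], size1 = tab$size[a],
        depth2 = tab$depth[b], size2 = tab$size[b], rel_diff = rel))
  }
  structure(list(table = tab,
                 near_pairs = if (is.null(near))
                   data.frame(depth1 = numeric(0), size1 = numeric(0),
                              depth2 = numeric(0), size2 = numeric(0),
                              rel_diff = numeric(0)) else near,
                 indentation_depth = indentation_depth),
            class = "ambiguity_envelope")
}
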