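#' Indentation protocol
#'
#' Describes a displacement-controlled palpation protocol: a rigid circular
#' indenter (the 2D cross-section of a spherical-tipped probe) driven
#' quasi-statically to one or more indentation depths at a set of surface
#' positions.
#'
#' @param positions surface x-coordinates (mm) to probe, strictly ascending.
#' @param depths indentation depths U (mm), strictly positive and ascending.
#' @param indenter_radius radius of the circular indenter cross-section (mm);
#'   5 mm for the 10-mm spherical-tip probe.
#' @param increments number of equal quasi-static displacement increments
#'   used to reach each depth.
#' @return An object of class `indentation_protocol`.
#' @export
indentation_protocol <- function(positions, depths, indenter_radius = 5,
                                 increments = 10) {
  stopifnot(is.numeric(positions), is.numeric(depths))
  if (indenter_radius <= 0) stop("indenter_radius must be positive")
  if (any(depths <= 0) || is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly positive and ascending")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly ascending")
  if (increments < 1) stop("increments must be >= 1")
  structure(list(positions = as.numeric(positions),
                 depths = as.numeric(depths),
                 indenter_radius = indenter_radius,
                 increments = as.integer(increments)),
            class = "indentation_protocol")
}

#' Equally spaced interior probe positions
#'
#' @param width domain width (mm).
#' @param n number of probe locations.
#' @return `n` equally spaced positions strictly inside `[0, width]`.
#' @export
probe_positions <- function(width, n) width * seq_len(n) / (n + 1)

# Materials table for the element kernel: one row per label code
# (1 = healthy, 2 = cancerous, 3 = interface mixture).  When a mixture
# material is not given it defaults to the arithmetic-mean modulus of the
# other two (valid here because both share the same Ogden exponents).
fem_materials_table <- function(materials, penalty_factor = 200) {
  stopifnot(is.list(materials), !is.null(materials$healthy),
            !is.null(materials$cancer))
  rh <- fem_material_row(materials$healthy, penalty_factor)
  rc <- fem_material_row(materials$cancer, penalty_factor)
  if (!is.null(materials$mixture)) {
    rm_ <- fem_material_row(materials$mixture, penalty_factor)
  } else {
    if (any(abs(rh[c(2, 4)] - rc[c(2, 4)]) > 1e-12))
      stop("cannot derive a mixture material: Ogden exponents differ")
    rm_ <- c((rh[1] + rc[1]) / 2, rh[2], (rh[3] + rc[3]) / 2, rh[4],
             (rh[5] + rc[5]) / 2)
  }
  rbind(rh, rc, rm_, deparse.level = 0)
}

# Full nonlinear solve of one indentation; returns force and solution state.
# The material is elastic, so the response is path independent: when
# `record_depths` is given, the indenter is driven quasi-statically to the
# final depth and the force recorded as the loading path passes through each
# requested depth (the schedule is augmented so it hits them exactly), which
# is identical to solving each depth from the undeformed state.
indent_solve <- function(mesh, materials, position, depth,
                         indenter_radius = 5, increments = 10,
                         mode = c("displacement", "penalty"),
                         penalty_factor = 200, contact_penalty = NULL,
                         tol = 1e-8, max_newton = 30, record_depths = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "palp_mesh"), depth >= 0)
  if (position < 0 || position > mesh$domain$width)
    stop("indentation position outside the domain surface")
  mats <- if (is.matrix(materials)) materials else
    fem_materials_table(materials, penalty_factor)
  cellmat <- mesh$labels + 1L
  N <- nrow(mesh$coords)
  u <- numeric(2 * N)
  if (depth == 0)
    return(list(force = 0, fx = 0, energy = 0, u = u, converged = TRUE,
                work = 0, recorded = numeric(length(record_depths))))

  mu0 <- mats[1, 1] + mats[1, 3]
  if (is.null(contact_penalty)) contact_penalty <- 1000 * mu0

  bottom <- mesh$bottom_nodes
  fixed_base <- c(2 * bottom - 1, 2 * bottom)   # both dofs of bottom nodes
  topx <- mesh$coords[mesh$top_nodes, 1]
  R <- indenter_radius

  steps <- seq(depth / increments, depth, length.out = increments)
  if (!is.null(record_depths)) {
    stopifnot(all(record_depths > 0), all(record_depths <= depth))
    steps <- sort(unique(c(steps, record_depths)))
  }
  increments <- length(steps)
  force_hist <- numeric(increments)
  force <- 0; fx <- 0; energy <- 0
  prev <- 0

  # secant predictor state: last two converged (uk, u) pairs
  u_last <- NULL; uk_last <- 0
  u_before <- NULL; uk_before <- NA_real_

  # try to converge the solution at indenter depth uk, restoring the last
  # converged state on failure
  attempt <- function(uk) {
    u0 <- u
    # extrapolate the previous incremental displacement field (free dofs);
    # prescribed dofs are overwritten below and wrong guesses only cost
    # Newton iterations, not correctness
    if (!is.null(u_before) && uk_last > uk_before) {
      fac <- (uk - uk_last) / (uk_last - uk_before)
      if (fac > 0 && fac < 2) u <<- u + fac * (u_last - u_before)
    }
    yc <- uk - R                      # indenter centre depth (y downward)
    if (mode == "displacement") {
      dx <- topx - position
      varc <- yc + sqrt(pmax(R^2 - dx^2, 0))
      inside <- abs(dx) < R & varc > 0
      contact_idx <- mesh$top_nodes[inside]
      if (!length(contact_idx)) {
        # the overlap is still narrower than the surface node spacing: the
        # indenter has not engaged the discretized surface, so the reaction
        # is zero and the state unchanged
        force <<- 0; fx <<- 0; energy <<- 0
        prev <<- uk
        return(TRUE)
      }
      fixed <- c(fixed_base, 2 * contact_idx)
      u[fixed] <<- c(numeric(length(fixed_base)), varc[inside])
      sol <- newton_solve(mesh, cellmat, mats, u, fixed, tol, max_newton,
                          contact = NULL)
      if (!sol$converged) { u <<- u0; return(FALSE) }
      u <<- sol$u
      force <<- sum(sol$residual[2 * contact_idx])
      fx <<- sum(sol$residual[2 * contact_idx - 1])
    } else {
      contact <- list(nodes = mesh$top_nodes, cx = position, cy = yc, R = R,
                      k = contact_penalty)
      sol <- newton_solve(mesh, cellmat, mats, u, fixed_base, tol, max_newton,
                          contact = contact)
      if (!sol$converged) { u <<- u0; return(FALSE) }
      u <<- sol$u
      cf <- contact_forces(mesh, u, contact)
      force <<- cf$fy
      fx <<- cf$fx
    }
    energy <<- sol$energy
    u_before <<- u_last; uk_before <<- uk_last
    u_last <<- u; uk_last <<- uk
    prev <<- uk
    TRUE
  }
  # quasi-static advance with recursive increment subdivision
  advance <- function(target, level = 0) {
    if (attempt(target)) return(invisible(TRUE))
    if (level >= 6)
      stop(sprintf(paste0("Newton divergence near indenter depth %.4g mm ",
                          "(position %.3g mm) despite increment subdivision"),
                   target, position))
    advance((prev + target) / 2, level + 1)
    advance(target, level + 1)
  }
  for (s in seq_along(steps)) {
    advance(steps[s])
    force_hist[s] <- force
  }
  dU <- diff(c(0, steps))
  work <- sum((c(0, force_hist[-increments]) + force_hist) / 2 * dU)
  recorded <- if (is.null(record_depths)) NULL else
    force_hist[match(record_depths, steps)]
  # the Newton loop churns large sparse factors; R's collector lags behind
  # their actual size, so collect before returning
  gc(verbose = FALSE, full = FALSE)
  list(force = force, fx = fx, energy = energy, u = u, converged = TRUE,
       work = work, force_hist = force_hist, steps = steps,
       recorded = recorded)
}

# penalty contact force/stiffness of top-surface nodes against the rigid circle
contact_eval <- function(mesh, u, contact) {
  nd <- contact$nodes
  px <- mesh$coords[nd, 1] + u[2 * nd - 1]
  py <- mesh$coords[nd, 2] + u[2 * nd]
  ddx <- px - contact$cx
  ddy <- py - contact$cy
  d <- sqrt(ddx^2 + ddy^2)
  g <- contact$R - d
  act <- which(g > 0 & d > 1e-12)
  list(act = nd[act], g = g[act], d = d[act],
       nx = ddx[act] / d[act], ny = ddy[act] / d[act])
}

contact_forces <- function(mesh, u, contact) {
  ce <- contact_eval(mesh, u, contact)
  k <- contact$k
  list(fy = sum(k * ce$g * ce$ny), fx = sum(k * ce$g * ce$nx))
}

# Newton iteration for fixed Dirichlet set (values already loaded into u).
# Globalized by an Armijo backtracking line search on the total potential
# energy (the residual is the exact gradient of the assembled energy) with a
# Levenberg-style diagonal shift whenever the Hessian is indefinite, so every
# step is a descent step.
newton_solve <- function(mesh, cellmat, mats, u, fixed, tol, max_newton,
                         contact = NULL) {
  N <- nrow(mesh$coords)
  free_mask <- rep(TRUE, 2 * N)
  free_mask[fixed] <- FALSE
  free <- which(free_mask)
  nf <- length(free)
  dofmap <- integer(2 * N)
  dofmap[free] <- seq_len(nf)

  eval_state <- function(uv, want_K) {
    asm <- fem_assemble(mesh$coords, mesh$cells, cellmat, mats, uv, want_K)
    if (!asm$ok) return(NULL)
    res <- asm$residual
    E <- asm$energy
    if (!is.null(contact)) {
      ca <- contact_residual(mesh, uv, contact, N, want_K = want_K)
      res <- res + ca$r
      E <- E + ca$E
      if (want_K) asm$Kc <- ca$K
    }
    asm$residual <- res
    asm$energy <- E
    asm
  }

  asm <- eval_state(u, TRUE)
  if (is.null(asm))   # inverted elements right after the increment jump
    return(list(u = u, residual = numeric(2 * N), energy = NA_real_,
                converged = FALSE, resnorm = Inf))
  scale0 <- max(1, sqrt(sum(asm$residual[fixed]^2)))
  converged <- FALSE
  resnorm <- Inf
  keep <- NULL
  dscale <- NULL
  for (it in seq_len(max_newton)) {
    rf <- asm$residual[free]
    resnorm <- sqrt(sum(rf^2))
    scale0 <- max(scale0, sqrt(sum(asm$residual[fixed]^2)))
    if (isTRUE(getOption("palpquant.newton_trace")))
      message(sprintf("  newton it %d resnorm %.3e scale %.3e", it, resnorm,
                      scale0))
    if (resnorm < tol * scale0 + 1e-12) { converged <- TRUE; break }
    # reduced symmetric tangent straight from the lower-triangle triplets
    # (the pattern is fixed for the whole solve, so the filter is computed
    # once; the FD asymmetry of the deviatoric block is ~1e-8 relative)
    if (is.null(keep)) {
      keep <- which(free_mask[asm$ki] & free_mask[asm$kj] &
                      asm$ki >= asm$kj)
      ii <- dofmap[asm$ki[keep]]
      jj <- dofmap[asm$kj[keep]]
    }
    vv <- asm$kv[keep]
    Ks <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nf, nf),
                               symmetric = TRUE)
    if (!is.null(asm$Kc))
      Ks <- Ks + Matrix::forceSymmetric(asm$Kc[free, free, drop = FALSE])
    if (is.null(dscale)) dscale <- mean(abs(Matrix::diag(Ks)))
    # simplicial LDL' factors indefinite matrices without failing; negative
    # pivots flag indefiniteness and trigger a Levenberg-style shift so the
    # step stays a descent direction
    tau <- 0
    du <- NULL
    for (trial in 1:12) {
      M <- if (tau > 0) Ks + (tau * dscale) * Matrix::Diagonal(nf) else Ks
      ch <- tryCatch(
        suppressWarnings(Matrix::Cholesky(M, LDL = TRUE, super = FALSE)),
        error = function(e) NULL)
      if (!is.null(ch) && !any(Matrix::diag(ch) <= 0)) {
        du <- as.numeric(Matrix::solve(ch, -rf))
        if (all(is.finite(du))) break
        du <- NULL
      }
      tau <- if (tau == 0) 1e-6 else 30 * tau
    }
    if (is.null(du)) break
    gTd <- sum(rf * du)          # directional derivative (negative)
    if (!is.finite(gTd) || gTd >= 0) break
    step <- 1
    accepted <- FALSE
    while (step >= 2^-14) {
      u_try <- u
      u_try[free] <- u[free] + step * du
      asm_try <- eval_state(u_try, FALSE)
      if (!is.null(asm_try) &&
          asm_try$energy <= asm$energy + 1e-4 * step * gTd) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break   # stagnation: caller subdivides the increment
    u <- u_try
    asm <- eval_state(u, TRUE)
    if (is.null(asm))
      return(list(u = u, residual = numeric(2 * N), energy = NA_real_,
                  converged = FALSE, resnorm = Inf))
  }
  list(u = u, residual = asm$residual, energy = asm$energy,
       converged = converged, resnorm = resnorm)
}

contact_residual <- function(mesh, u, contact, N, want_K = TRUE) {
  ce <- contact_eval(mesh, u, contact)
  r <- numeric(2 * N)
  k <- contact$k
  if (!length(ce$act))
    return(list(r = r, E = 0, K = if (want_K)
      Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(2 * N, 2 * N))))
  ix <- 2 * ce$act - 1
  iy <- 2 * ce$act
  # dE/du for E = k/2 g^2, g = R - |x - c|
  r[ix] <- -k * ce$g * ce$nx
  r[iy] <- -k * ce$g * ce$ny
  K <- NULL
  if (want_K) {
    # Hessian: k n n^T - (k g / d)(I - n n^T), per node
    h11 <- k * ce$nx^2 - k * ce$g / ce$d * (1 - ce$nx^2)
    h22 <- k * ce$ny^2 - k * ce$g / ce$d * (1 - ce$ny^2)
    h12 <- k * ce$nx * ce$ny + k * ce$g / ce$d * ce$nx * ce$ny
    K <- Matrix::sparseMatrix(i = c(ix, iy, ix, iy),
                              j = c(ix, iy, iy, ix),
                              x = c(h11, h22, h12, h12),
                              dims = c(2 * N, 2 * N))
  }
  list(r = r, E = sum(k / 2 * ce$g^2), K = K)
}

#' Simulate a single indentation
#'
#' Drives a rigid, frictionless circular indenter quasi-statically into the
#' top surface at one position and depth and returns the total vertical
#' reaction force on the indenter, per unit out-of-plane thickness.  The
#' bottom edge is fully fixed and the lateral edges are traction-free; each
#' call starts from the undeformed configuration.
#'
#' @param mesh a [palp_mesh][build_mesh()].
#' @param materials list with components `healthy`, `cancer` and optionally
#'   `mixture`, each an [ogden_material()] or [neo_hookean_material()].
#' @param position surface x-coordinate of the indenter axis (mm).
#' @param depth indentation depth (mm).
#' @param indenter_radius indenter radius (mm).
#' @param increments number of equal displacement increments.
#' @param mode `"displacement"` (fast: surface nodes inside the geometric
#'   overlap are moved onto the indenter arc, vertical component only, which
#'   leaves the horizontal dof free and is therefore frictionless) or
#'   `"penalty"` (frictionless nodal penalty contact against the analytic
#'   rigid circle).
#' @param penalty_factor volumetric penalty bulk modulus as a multiple of the
#'   initial shear modulus.
#' @param contact_penalty contact penalty stiffness (N/mm per mm penetration);
#'   default scales with the tissue shear modulus.
#' @param tol relative Newton convergence tolerance.
#' @param details if `TRUE`, return the full solution state (displacements,
#'   strain energy, external work, horizontal force) instead of the force.
#' @return The vertical force (N/mm), or a list when `details = TRUE`.
#' @export
indent_once <- function(mesh, materials, position, depth,
                        indenter_radius = 5, increments = 10,
                        mode = c("displacement", "penalty"),
                        penalty_factor = 200, contact_penalty = NULL,
                        tol = 1e-8, details = FALSE) {
  sol <- indent_solve(mesh, materials, position, depth,
                      indenter_radius = indenter_radius,
                      increments = increments, mode = match.arg(mode),
                      penalty_factor = penalty_factor,
                      contact_penalty = contact_penalty, tol = tol)
  if (details) sol else sol$force
}

#' Sweep a palpation protocol across the surface
#'
#' Runs [indent_once()] at every (position, depth) combination of the
#' protocol, each from a fresh undeformed configuration (indentations are
#' independent, emulating an experimental relaxation protocol), and collects
#' one force profile per indentation depth.
#'
#' @param mesh a [palp_mesh][build_mesh()].
#' @param materials material list as in [indent_once()].
#' @param protocol an [indentation_protocol()].
#' @param ... further arguments passed to [indent_once()].
#' @return List of [force_profile()] objects, one per indentation depth,
#'   tagged `source = "simulated"`.
#' @export
sweep_indent <- function(mesh, materials, protocol, ...) {
  stopifnot(inherits(protocol, "indentation_protocol"))
  dmax <- max(protocol$depths)
  fmat <- vapply(protocol$positions, function(px) {
    sol <- tryCatch(
      indent_solve(mesh, materials, px, dmax,
                   indenter_radius = protocol$indenter_radius,
                   increments = protocol$increments,
                   record_depths = protocol$depths, ...),
      error = function(e)
        stop(sprintf("indentation failed at position %.3g mm: %s",
                     px, conditionMessage(e))))
    sol$recorded
  }, numeric(length(protocol$depths)))
  fmat <- matrix(fmat, nrow = length(protocol$depths))
  lapply(seq_along(protocol$depths), function(k)
    force_profile(indentation_depth = protocol$depths[k],
                  positions = protocol$positions,
                  forces = fmat[k, ], source = "simulated"))
}
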