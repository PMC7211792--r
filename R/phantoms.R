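#' Nodule geometry specification
#'
#' Parametric description of a stiff nodule embedded in the tissue block.
#' Supported shapes:
#' \describe{
#'   \item{`circle`}{`diameter` (mm).}
#'   \item{`intersecting_circles`}{`diameters` (two values, mm) and `offset`
#'     (centre-to-centre distance, mm; defaults to the mean radius so the
#'     circles genuinely intersect). Both centres lie at the nodule depth,
#'     side by side.}
#'   \item{`polygon`}{`vertices`: two-column matrix of (x, y) offsets (mm)
#'     relative to the nodule centre; must be simple (non self-intersecting).}
#'   \item{`diffuse_annulus`}{`inner_diameter`, `outer_diameter` (mm): a
#'     cancerous core surrounded by a shell of mixed healthy/cancerous
#'     tissue.}
#'   \item{`rectangle`}{`width`, `height` (mm).}
#'   \item{`none`}{homogeneous block.}
#' }
#'
#' @param shape one of the shapes above.
#' @param depth nodule depth (mm), measured per `depth_reference`.
#' @param x nodule centre x-coordinate (mm).
#' @param depth_reference `"center"` (depth of the geometric centre) or
#'   `"top"` (depth of the uppermost point).
#' @param ... shape parameters as described above.
#' @return An object of class `nodule_spec`.
#' @examples
#' nodule_spec("circle", depth = 30, x = 50, diameter = 16)
#' @export
nodule_spec <- function(shape = c("circle", "intersecting_circles", "polygon",
                                  "diffuse_annulus", "rectangle", "none"),
                        depth = NA_real_, x = NA_real_,
                        depth_reference = c("center", "top"), ...) {
  shape <- match.arg(shape)
  depth_reference <- match.arg(depth_reference)
  pars <- list(...)
  if (shape != "none") {
    stopifnot(is.numeric(depth), depth > 0, is.numeric(x))
    need <- switch(shape,
      circle = "diameter",
      intersecting_circles = "diameters",
      polygon = "vertices",
      diffuse_annulus = c("inner_diameter", "outer_diameter"),
      rectangle = c("width", "height"))
    miss <- setdiff(need, names(pars))
    if (length(miss))
      stop("missing shape parameters: ", paste(miss, collapse = ", "))
    num <- unlist(pars[setdiff(need, "vertices")])
    if (length(num) && any(num <= 0)) stop("shape dimensions must be positive")
    if (shape == "intersecting_circles") {
      if (length(pars$diameters) != 2) stop("diameters must have length 2")
      if (is.null(pars$offset)) pars$offset <- mean(pars$diameters) / 2
      r <- pars$diameters / 2
      if (pars$offset <= abs(r[1] - r[2]) || pars$offset >= sum(r))
        stop("circles must properly intersect")
    }
    if (shape == "diffuse_annulus" &&
        pars$inner_diameter >= pars$outer_diameter)
      stop("inner_diameter must be smaller than outer_diameter")
    if (shape == "polygon") {
      v <- as.matrix(pars$vertices)
      if (ncol(v) != 2 || nrow(v) < 3) stop("vertices must be an n x 2 matrix")
      if (polygon_self_intersects(v)) stop("polygon is self-intersecting")
      pars$vertices <- v
    }
  }
  structure(c(list(shape = shape, depth = depth, x = x,
                   depth_reference = depth_reference), pars),
            class = "nodule_spec")
}

# y-coordinate of the shape centre, honouring the depth reference
nodule_center_y <- function(spec) {
  if (spec$depth_reference == "center") return(spec$depth)
  half <- switch(spec$shape,
    circle = spec$diameter / 2,
    intersecting_circles = max(spec$diameters) / 2,
    diffuse_annulus = spec$outer_diameter / 2,
    rectangle = spec$height / 2,
    polygon = -min(spec$vertices[, 2]),
    none = 0)
  spec$depth + half
}

# axis-aligned bounding box in domain coordinates
nodule_bbox <- function(spec) {
  cy <- nodule_center_y(spec)
  cx <- spec$x
  half <- switch(spec$shape,
    circle = c(spec$diameter, spec$diameter) / 2,
    intersecting_circles = {
      r <- spec$diameters / 2
      c(spec$offset / 2 + max(r), max(r))
    },
    diffuse_annulus = c(spec$outer_diameter, spec$outer_diameter) / 2,
    rectangle = c(spec$width, spec$height) / 2,
    polygon = c(max(abs(spec$vertices[, 1])), max(abs(spec$vertices[, 2]))),
    none = c(0, 0))
  if (spec$shape == "polygon") {
    c(xmin = cx + min(spec$vertices[, 1]), xmax = cx + max(spec$vertices[, 1]),
      ymin = cy + min(spec$vertices[, 2]), ymax = cy + max(spec$vertices[, 2]))
  } else {
    c(xmin = cx - half[1], xmax = cx + half[1],
      ymin = cy - half[2], ymax = cy + half[2])
  }
}

# label code (0 healthy / 1 cancer / 2 mixture) at query points, vectorized
nodule_region <- function(spec, px, py) {
  out <- rep(.LAB_HEALTHY, length(px))
  if (spec$shape == "none") return(out)
  cy <- nodule_center_y(spec)
  cx <- spec$x
  switch(spec$shape,
    circle = {
      out[(px - cx)^2 + (py - cy)^2 <= (spec$diameter / 2)^2] <- .LAB_CANCER
    },
    intersecting_circles = {
      r <- spec$diameters / 2
      c1 <- cx - spec$offset / 2
      c2 <- cx + spec$offset / 2
      inn <- (px - c1)^2 + (py - cy)^2 <= r[1]^2 |
             (px - c2)^2 + (py - cy)^2 <= r[2]^2
      out[inn] <- .LAB_CANCER
    },
    rectangle = {
      out[abs(px - cx) <= spec$width / 2 &
          abs(py - cy) <= spec$height / 2] <- .LAB_CANCER
    },
    diffuse_annulus = {
      d2 <- (px - cx)^2 + (py - cy)^2
      out[d2 <= (spec$outer_diameter / 2)^2] <- .LAB_MIXTURE
      out[d2 <= (spec$inner_diameter / 2)^2] <- .LAB_CANCER
    },
    polygon = {
      bnd <- cbind(spec$vertices[, 1] + cx, spec$vertices[, 2] + cy)
      out[mgcv::in.out(bnd, cbind(px, py))] <- .LAB_CANCER
    })
  out
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) == 1 || (i == 1 && j == n)) next
    a <- seg[i, ]; b <- seg[j, ]
    d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
    d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
    d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
    d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
    if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
  }
  FALSE
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Discretize a nodule into a polygonal boundary
#'
#' Converts a [nodule_spec()] into closed polygonal boundaries (circular arcs
#' sampled at a configurable angular resolution) with the enclosed area
#' attached.  For the diffuse annulus both the outer (mixture) and inner
#' (cancerous core) boundaries are returned with their areas.
#'
#' @param spec a [nodule_spec()].
#' @param angular_resolution arc sampling step in degrees.
#' @return A list with `boundary` (n x 2 matrix, domain coordinates),
#'   `area` (mm^2, of the outermost boundary), and for the annulus
#'   additionally `inner_boundary` and `core_area`.
#' @export
make_nodule <- function(spec, angular_resolution = 1) {
  stopifnot(inherits(spec, "nodule_spec"))
  if (spec$shape == "none")
    return(list(boundary = NULL, area = 0))
  cy <- nodule_center_y(spec)
  cx <- spec$x
  circ <- function(c0, r, from = 0, to = 2 * pi) {
    th <- seq(from, to,
              length.out = max(8, ceiling((to - from) /
                                            (angular_resolution * pi / 180))))
    cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
  }
  out <- switch(spec$shape,
    circle = {
      b <- circ(c(cx, cy), spec$diameter / 2)
      list(boundary = b[-nrow(b), ])
    },
    rectangle = {
      w <- spec$width / 2; h <- spec$height / 2
      list(boundary = cbind(cx + c(-w, w, w, -w), cy + c(-h, -h, h, h)))
    },
    polygon = {
      list(boundary = cbind(spec$vertices[, 1] + cx, spec$vertices[, 2] + cy))
    },
    diffuse_annulus = {
      bo <- circ(c(cx, cy), spec$outer_diameter / 2)
      bi <- circ(c(cx, cy), spec$inner_diameter / 2)
      list(boundary = bo[-nrow(bo), ], inner_boundary = bi[-nrow(bi), ],
           core_area = shoelace_area(bi[-nrow(bi), ]))
    },
    intersecting_circles = {
      r <- spec$diameters / 2
      c1 <- c(cx - spec$offset / 2, cy)
      c2 <- c(cx + spec$offset / 2, cy)
      d <- spec$offset
      # half-angles subtended by the chord of intersection at each centre
      b1 <- acos((d^2 + r[1]^2 - r[2]^2) / (2 * d * r[1]))
      b2 <- acos((d^2 + r[2]^2 - r[1]^2) / (2 * d * r[2]))
      # boundary of circle 1 lying outside circle 2 (facing away from c2,
      # which lies at angle 0 from c1), then vice versa
      a1 <- circ(c1, r[1], from = b1, to = 2 * pi - b1)
      a2 <- circ(c2, r[2], from = -pi + b2, to = pi - b2)
      list(boundary = rbind(a1[-nrow(a1), ], a2[-nrow(a2), ]))
    })
  out$area <- shoelace_area(out$boundary)
  out$spec <- spec
  out
}

#' True cross-sectional area of a nodule
#'
#' Area of the nodule's cancerous region computed from the discretized
#' boundary (within the angular-resolution tolerance for curved shapes).
#'
#' @param spec a [nodule_spec()].
#' @return Area in mm^2.
#' @export
nodule_area <- function(spec) {
  if (spec$shape == "none") return(0)
  make_nodule(spec, angular_resolution = 0.25)$area
}

#' Measurement noise model for synthetic palpation
#'
#' @param sigma standard deviation of the zero-mean Gaussian force noise, as
#'   a fraction of the per-profile maximum force.
#' @param contact_offset half-width (mm) of the uniform random
#'   indentation-depth offset emulating contact-point-finding error; one
#'   offset is drawn per probe position (the contact is found once per site)
#'   and applied across its indentation depths.  Bounded by 0.5 mm.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, contact_offset = 0, seed = 1L) {
  stopifnot(sigma >= 0, contact_offset >= 0)
  if (contact_offset > 0.5)
    stop("contact_offset is bounded by 0.5 mm")
  structure(list(sigma = sigma, contact_offset = contact_offset,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Registry of ready-made simulation bundles
#'
#' Named bundles that fully instantiate the pipeline: a tissue domain, a
#' nodule geometry, materials and an indentation protocol.  Included are the
#' two in-silico worked examples (16-mm circle at 30 mm depth; 30-mm circle
#' at 45 mm depth, both probed at 1/5/10 mm indentation depths over 40
#' locations of a 100 x 100 mm block of 20/40 kPa Ogden tissue), the five
#' nodule-geometry sensitivity cases (two intersecting-circle variants, an
#' irregular polygon, a diffuse-boundary annulus, and a rectangle), and the
#' 2D mid-section of the gelatin tissue phantom (100 x 31 mm block,
#' 20 x 12 mm rectangular nodule with its top face 10 mm below the surface,
#' neo-Hookean gels of 28.1 and 39.5 kPa, indentation depths 2/4/6 mm at 5
#' sites).
#'
#' The irregular polygon is a fixed synthetic stand-in of roughly 15 mm
#' extent (irregular nodule outlines are not standardized); the
#' intersecting-circle centre offset defaults to the mean radius so the
#' circles genuinely intersect; both choices are recorded in the bundle
#' metadata.
#'
#' @param mesh_size mesh size (mm) used in every bundle's domain.
#' @return Named list of bundles; each bundle has `domain`, `nodule`,
#'   `materials`, `protocol` and `meta`.
#' @export
reference_configurations <- function(mesh_size = 5) {
  og_h <- ogden_healthy_tissue()
  og_c <- ogden_cancerous_nodule()
  insilico <- function(nod, name, note = NULL) {
    list(name = name,
         domain = tissue_domain(100, 100, mesh_size),
         nodule = nod,
         materials = list(healthy = og_h, cancer = og_c),
         protocol = indentation_protocol(positions = probe_positions(100, 40),
                                         depths = c(1, 5, 10)),
         meta = c(list(equivalent_moduli_kpa = c(20, 40)), note))
  }
  # fixed irregular outline, ~15 mm extent (synthetic stand-in)
  blob <- cbind(
    x = c(7.5, 5.0, 1.5, -2.5, -6.5, -7.5, -5.5, -1.0, 3.0, 6.0),
    y = c(0.0, 4.5, 6.5, 5.5, 3.0, -1.5, -5.5, -7.0, -5.0, -3.0))
  reg <- list(
    insilico_example1 = insilico(
      nodule_spec("circle", depth = 30, x = 50, diameter = 16),
      "insilico_example1"),
    insilico_example2 = insilico(
      nodule_spec("circle", depth = 45, x = 50, diameter = 30),
      "insilico_example2"),
    intersecting_circles_a = insilico(
      nodule_spec("intersecting_circles", depth = 30, x = 50,
                  diameters = c(10, 15)),
      "intersecting_circles_a",
      note = list(offset_rule = "mean radius")),
    intersecting_circles_b = insilico(
      nodule_spec("intersecting_circles", depth = 40, x = 50,
                  diameters = c(15, 10)),
      "intersecting_circles_b",
      note = list(offset_rule = "mean radius")),
    irregular_polygon = insilico(
      nodule_spec("polygon", depth = 30, x = 50, vertices = blob),
      "irregular_polygon",
      note = list(stand_in = "fixed synthetic outline, ~15 mm extent")),
    diffuse_annulus = insilico(
      nodule_spec("diffuse_annulus", depth = 35, x = 50,
                  inner_diameter = 20, outer_diameter = 30),
      "diffuse_annulus",
      note = list(mixture_rule = "arithmetic mean of moduli")),
    rectangular_nodule = insilico(
      nodule_spec("rectangle", depth = 30, x = 50,
                  width = 12.5, height = 25),
      "rectangular_nodule"),
    gelatin_phantom_2d = list(
      name = "gelatin_phantom_2d",
      domain = tissue_domain(100, 31, min(mesh_size, 2.5)),
      nodule = nodule_spec("rectangle", depth = 10, x = 50,
                           depth_reference = "top",
                           width = 20, height = 12),
      materials = list(healthy = neo_hookean_material(4.6898e-3),
                       cancer = neo_hookean_material(6.5872e-3)),
      protocol = indentation_protocol(positions = probe_positions(100, 5),
                                      depths = c(2, 4, 6)),
      meta = list(section = "2D mid-section of a 100 x 31 x 60 mm block",
                  nodule_3d_mm = c(20, 12, 12),
                  young_moduli_kpa = c(28.1, 39.5)))
  )
  reg
}

#' Generate a synthetic palpation measurement
#'
#' Runs the forward simulation for a bundle and perturbs it with the noise
#' model: a per-position indentation-depth offset (applied by re-evaluating
#' a local monotone force-depth interpolant at `depth + offset`) emulating
#' contact-point-finding error, then zero-mean Gaussian force noise scaled
#' by the per-profile maximum force.  Forces driven negative are clipped at
#' zero (count reported in attribute `"clipped"`).  Fully reproducible from
#' the noise seed; with zero noise the output is identical to the plain
#' simulation.
#'
#' @param bundle a bundle from [reference_configurations()] or a list with
#'   `domain`, `nodule`, `materials`, `protocol`.
#' @param noise a [noise_model()].
#' @param mesh optional prebuilt mesh (rebuilt from the bundle otherwise).
#' @param ... passed to [sweep_indent()].
#' @return List of [force_profile()]s tagged `source = "synthetic"`.
#' @export
synth_measurement <- function(bundle, noise = noise_model(), mesh = NULL, ...) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(mesh)) mesh <- build_mesh(bundle$domain, bundle$nodule)
  profiles <- sweep_indent(mesh, bundle$materials, bundle$protocol, ...)
  clipped <- 0L
  if (noise$sigma > 0 || noise$contact_offset > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(noise$seed)
    npos <- length(bundle$protocol$positions)
    depths <- bundle$protocol$depths
    if (noise$contact_offset > 0) {
      off <- stats::runif(npos, -noise$contact_offset, noise$contact_offset)
      fmat <- sapply(profiles, function(p) p$forces)  # npos x ndepth
      fmat <- rbind(fmat)
      for (i in seq_len(npos)) {
        fd <- stats::splinefun(c(0, depths), c(0, fmat[i, ]),
                               method = "hyman")
        for (k in seq_along(depths))
          profiles[[k]]$forces[i] <- fd(max(0, depths[k] + off[i]))
      }
    }
    for (k in seq_along(profiles)) {
      f <- profiles[[k]]$forces
      if (noise$sigma > 0)
        f <- f + stats::rnorm(length(f), 0, noise$sigma * max(f))
      nneg <- sum(f < 0)
      if (nneg) {
        clipped <- clipped + nneg
        f[f < 0] <- 0
        warning(sprintf("%d negative force(s) clipped at 0", nneg))
      }
      profiles[[k]]$forces <- f
    }
  }
  profiles <- lapply(profiles, function(p) { p$source <- "synthetic"; p })
  attr(profiles, "clipped") <- clipped
  profiles
}
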