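#' Rectangular tissue domain
#'
#' Describes the 2D plane-strain tissue block that is palpated along its top
#' surface.  Coordinates: x in `[0, width]` along the palpated surface, y
#' positive downward from the top surface (so the "depth" of a feature is its
#' y coordinate).
#'
#' @param width domain width (mm).
#' @param height domain height (mm).
#' @param mesh_size target element edge length (mm).
#' @return An object of class `tissue_domain`.
#' @examples
#' tissue_domain(100, 100, mesh_size = 5)
#' @export
tissue_domain <- function(width = 100, height = 100, mesh_size = 5) {
  stopifnot(width > 0, height > 0, mesh_size > 0)
  if (mesh_size > min(width, height) / 4)
    stop("mesh_size too coarse for the domain")
  structure(list(width = width, height = height, mesh_size = mesh_size),
            class = "tissue_domain")
}

# material label codes used on mesh elements
.LAB_HEALTHY <- 0L
.LAB_CANCER <- 1L
.LAB_MIXTURE <- 2L

#' Build a crossed-triangle mesh with material labels
#'
#' Discretizes the domain into a structured grid of quadrilateral cells, each
#' split into four triangles around a centre node (the "crossed" pattern,
#' which behaves well under near-incompressibility).  Each triangle is
#' labelled healthy, cancerous or interface-mixture according to the position
#' of its centroid relative to the nodule geometry.
#'
#' @param domain a [tissue_domain()].
#' @param nodule a [nodule_spec()] or `NULL` for a homogeneous block.
#' @return An object of class `palp_mesh` with node coordinates, cell
#'   connectivity, per-triangle labels and surface node indices.
#' @export
build_mesh <- function(domain, nodule = NULL) {
  stopifnot(inherits(domain, "tissue_domain"))
  if (!is.null(nodule) && nodule$shape != "none") {
    stopifnot(inherits(nodule, "nodule_spec"))
    bb <- nodule_bbox(nodule)
    if (bb["xmin"] <= 0 || bb["xmax"] >= domain$width ||
        bb["ymin"] <= 0 || bb["ymax"] >= domain$height)
      stop("nodule must lie strictly inside the domain")
  }
  # x is resolved at mesh_size/2 across the whole palpated surface; rows are
  # graded in y: mesh_size/2 in the contact-affected band near the surface,
  # mesh_size in the middle, ~1.7*mesh_size at depth (contact accuracy is
  # governed by the surface resolution, the far field by equilibrium only)
  hx <- domain$mesh_size / 2
  nx <- max(8L, as.integer(round(domain$width / hx)))
  xg <- seq(0, domain$width, length.out = nx + 1)
  yg <- graded_rows(domain$height, domain$mesh_size)
  ny <- length(yg) - 1L
  grid <- cbind(rep(xg, times = ny + 1), rep(yg, each = nx + 1))
  cx <- (xg[-1] + xg[-(nx + 1)]) / 2
  cy <- (yg[-1] + yg[-(ny + 1)]) / 2
  centres <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  coords <- rbind(grid, centres)
  ngrid <- nrow(grid)

  gid <- function(i, j) j * (nx + 1L) + i + 1L              # i,j 0-based
  ii <- rep(0:(nx - 1L), times = ny)
  jj <- rep(0:(ny - 1L), each = nx)
  v0 <- gid(ii, jj); v1 <- gid(ii + 1L, jj)
  v2 <- gid(ii + 1L, jj + 1L); v3 <- gid(ii, jj + 1L)
  cc <- ngrid + jj * nx + ii + 1L
  cells <- cbind(v0, v1, v2, v3, cc)
  ncell <- nrow(cells)

  # centroid of each of the 4 triangles of every cell
  labels <- matrix(.LAB_HEALTHY, ncell, 4)
  if (!is.null(nodule) && nodule$shape != "none") {
    tri_local <- list(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
    for (t in 1:4) {
      idx <- cells[, tri_local[[t]]]
      px <- (coords[idx[, 1], 1] + coords[idx[, 2], 1] + coords[idx[, 3], 1]) / 3
      py <- (coords[idx[, 1], 2] + coords[idx[, 2], 2] + coords[idx[, 3], 2]) / 3
      labels[, t] <- nodule_region(nodule, px, py)
    }
  }

  # all four triangles of a cell have area hx*hy_row/4
  hy_row <- diff(yg)
  cell_tri_area <- rep(hx * hy_row / 4, each = nx)
  if (any(cell_tri_area <= 0)) stop("degenerate mesh")

  structure(list(coords = coords, cells = cells, labels = labels,
                 nx = nx, ny = ny, hx = hx, ybreaks = yg,
                 cell_tri_area = cell_tri_area,
                 top_nodes = which(coords[, 2] == 0),
                 bottom_nodes = which(coords[, 2] == domain$height),
                 domain = domain, nodule = nodule),
            class = "palp_mesh")
}

# graded row breaks: fine near the indented surface, coarser at depth
graded_rows <- function(height, mesh_size) {
  b1 <- min(12, 0.4 * height)
  n1 <- max(2L, ceiling(b1 / (mesh_size / 2)))
  b2 <- 0.65 * height
  n2 <- max(1L, ceiling((b2 - b1) / mesh_size))
  n3 <- max(1L, ceiling((height - b2) / (1.7 * mesh_size)))
  c(seq(0, b1, length.out = n1 + 1),
    seq(b1, b2, length.out = n2 + 1)[-1],
    seq(b2, height, length.out = n3 + 1)[-1])
}

#' Total element area per material label
#'
#' @param mesh a [palp_mesh][build_mesh()].
#' @return Named numeric vector of areas (mm^2) for labels `healthy`,
#'   `cancerous`, `mixture`.
#' @export
mesh_label_areas <- function(mesh) {
  stopifnot(inherits(mesh, "palp_mesh"))
  a <- rep(mesh$cell_tri_area, 4)
  lab <- as.integer(mesh$labels)
  c(healthy = sum(a[lab == .LAB_HEALTHY]),
    cancerous = sum(a[lab == .LAB_CANCER]),
    mixture = sum(a[lab == .LAB_MIXTURE]))
}

#' Export a mesh as legacy ASCII VTK
#'
#' Writes the crossed-triangle mesh (with its material labels as cell data)
#' in the legacy VTK unstructured-grid text format readable by ParaView and
#' meshio.
#'
#' @param mesh a [palp_mesh][build_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "palp_mesh"))
  tri_local <- list(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  tris <- do.call(rbind, lapply(tri_local, function(tl) mesh$cells[, tl]))
  labs <- as.integer(mesh$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "palpquant mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$coords))), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$coords[, 1], mesh$coords[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tris), 4 * nrow(tris)), con)
  writeLines(sprintf("3 %d %d %d", tris[, 1] - 1L, tris[, 2] - 1L,
                     tris[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tris)), con)
  writeLines(rep("5", nrow(tris)), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(tris)),
               "SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(labs), con)
  invisible(path)
}
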