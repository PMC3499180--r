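# Parameterised five-region domain and its structured quadrilateral mesh.
# Zones stack bottom-to-top along the growth direction (+y):
# metaphyseal bone, hypertrophic, proliferative, reserve, epiphyseal bone.
# Within the columnar zones one element row corresponds to one chondrocyte,
# and one element strip (40 um) to one cell column.

ZONE_ORDER <- c("metaphyseal_bone", "hypertrophic", "proliferative",
                "reserve", "epiphyseal_bone")
ZONE_TISSUE <- c(metaphyseal_bone = "trabecular_bone",
                 hypertrophic = "hypertrophic",
                 proliferative = "proliferative",
                 reserve = "reserve",
                 epiphyseal_bone = "trabecular_bone")

#' Build the five-region domain geometry for a load case
#'
#' Stacks the two trabecular bone regions and the three cartilage zones into
#' the square simulation domain.  The cartilage thicknesses come from the
#' load case; the epiphyseal and metaphyseal bone regions share the
#' remaining height equally, so the five thicknesses sum to the domain side
#' (800 um) at time zero.
#'
#' @param load_case A [get_load_case()] object.
#' @param constants Physiological constants, see [gp_constants()].
#' @return An object of class `gp_zone_geometry`: a list with `zones`
#'   (data frame: `zone`, `thickness`, `tissue`, bottom to top), `width`,
#'   `cells` (cells per column) and the growth direction `n`.
#' @export
#' @examples
#' build_domain(get_load_case(0))
build_domain <- function(load_case, constants = gp_constants()) {
  stopifnot(inherits(load_case, "gp_load_case"))
  side <- constants$domain_side
  cart <- sum(load_case$thickness)
  if (cart >= side) {
    stop("total cartilage thickness (", cart, " um) exceeds the domain ",
         "side (", side, " um)", call. = FALSE)
  }
  bone <- (side - cart) / 2
  zones <- data.frame(
    zone = ZONE_ORDER,
    thickness = c(bone,
                  load_case$thickness[["hypertrophic"]],
                  load_case$thickness[["proliferative"]],
                  load_case$thickness[["reserve"]],
                  bone),
    tissue = unname(ZONE_TISSUE[ZONE_ORDER]),
    stringsAsFactors = FALSE)
  structure(list(zones = zones, width = side, cells = load_case$cells,
                 n = c(0, 1)),
            class = "gp_zone_geometry")
}

#' @export
print.gp_zone_geometry <- function(x, ...) {
  cat("Five-region growth-plate domain (bottom to top):\n")
  print(x$zones, row.names = FALSE)
  cat(sprintf("  width %.0f um, total height %.1f um\n",
              x$width, sum(x$zones$thickness)))
  invisible(x)
}

#' Generate the structured quadrilateral mesh
#'
#' Structured, axis-aligned 4-node quadrilateral grid over the five-region
#' domain.  Laterally the mesh is tied to the chondrocyte columns: each
#' 40 um column strip holds `lateral_per_column` element columns.  In the
#' growth direction the columnar cartilage zones get one element row per
#' chondrocyte (so each element holds one cell, anisotropy ratio 1/1),
#' while the non-growing reserve and bone regions get a fixed number of
#' rows, enough to transmit the load.
#'
#' @param geometry A [build_domain()] object.
#' @param columns Number of chondrocyte columns.
#' @param spacing Column spacing, um; `columns * spacing` must not exceed
#'   the domain width (with the defaults it tiles it exactly).
#' @param lateral_per_column Element columns per cell column.
#' @param reserve_rows,bone_rows Element rows in the reserve zone and in
#'   each bone region.
#' @return An object of class `gp_mesh`: node coordinates, counter-clockwise
#'   element connectivity, the structured-grid line positions, and
#'   element-to-zone / tissue / cell-column maps.
#' @export
generate_mesh <- function(geometry, columns = gp_constants()$columns,
                          spacing = gp_constants()$column_spacing,
                          lateral_per_column = 1,
                          reserve_rows = 2, bone_rows = 2) {
  stopifnot(inherits(geometry, "gp_zone_geometry"),
            columns >= 1, spacing > 0, lateral_per_column >= 1)
  if (columns * spacing > geometry$width + 1e-9) {
    stop("columns * spacing exceeds the domain width", call. = FALSE)
  }
  rows_per_zone <- c(metaphyseal_bone = bone_rows,
                     hypertrophic = geometry$cells[["hypertrophic"]],
                     proliferative = geometry$cells[["proliferative"]],
                     reserve = reserve_rows,
                     epiphyseal_bone = bone_rows)
  thick <- setNames(geometry$zones$thickness, geometry$zones$zone)
  if (any(thick[names(rows_per_zone)] <= 0)) {
    stop("degenerate (zero-thickness) zone cannot be meshed", call. = FALSE)
  }

  nx <- columns * lateral_per_column
  x_lines <- seq(0, columns * spacing, length.out = nx + 1)
  y_lines <- 0
  row_zone <- integer(0)
  for (z in seq_along(ZONE_ORDER)) {
    nz <- rows_per_zone[[ZONE_ORDER[z]]]
    y_lines <- c(y_lines,
                 y_lines[length(y_lines)] +
                   seq_len(nz) * (thick[[ZONE_ORDER[z]]] / nz))
    row_zone <- c(row_zone, rep(z, nz))
  }
  ny <- length(row_zone)

  mesh <- structure(list(nx = nx, ny = ny,
                         x_lines = x_lines, y_lines = y_lines,
                         row_zone = row_zone,
                         zones = geometry$zones,
                         spacing = spacing,
                         lateral_per_column = lateral_per_column,
                         n = geometry$n),
                    class = "gp_mesh")
  mesh <- .mesh_rebuild_nodes(mesh)

  elem_zone <- rep(row_zone, each = nx)
  xc <- (x_lines[-1] + x_lines[-(nx + 1)]) / 2
  col_of_x <- pmin(columns, floor(xc / spacing) + 1L)  # half-open strips
  columnar <- ZONE_ORDER[elem_zone] %in% c("proliferative", "hypertrophic")
  elem_column <- rep(col_of_x, times = ny)
  elem_column[!columnar] <- NA_integer_
  mesh$elem_zone <- elem_zone
  mesh$elem_tissue <- geometry$zones$tissue[elem_zone]
  mesh$elem_column <- elem_column
  mesh
}

# Rebuild node coordinates and connectivity from the grid lines.
.mesh_rebuild_nodes <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  nodes <- cbind(x = rep(mesh$x_lines, times = ny + 1),
                 y = rep(mesh$y_lines, each = nx + 1))
  r <- rep(seq_len(ny), each = nx)
  c_ <- rep(seq_len(nx), times = ny)
  n1 <- (r - 1L) * (nx + 1L) + c_
  mesh$nodes <- nodes
  mesh$elems <- cbind(n1, n1 + 1L, n1 + nx + 2L, n1 + nx + 1L)  # ccw
  mesh
}

#' Update the mesh geometry after a growth increment
#'
#' Lagrangian geometry update: each growing zone's element rows are
#' stretched uniformly by its elongation increment and all material above
#' is translated upward, so topology, conformity and the element maps are
#' untouched.  Two successive increments compose exactly like their sum.
#'
#' @param mesh A `gp_mesh`.
#' @param growth_increment Named numeric vector of elongations in um, names
#'   among the zone names (typically `proliferative`, `hypertrophic`);
#'   increments must be non-negative.
#' @return The updated `gp_mesh`.
#' @export
update_geometry <- function(mesh, growth_increment) {
  stopifnot(inherits(mesh, "gp_mesh"))
  if (length(growth_increment) == 0) return(mesh)
  if (is.null(names(growth_increment)) ||
      !all(names(growth_increment) %in% ZONE_ORDER)) {
    stop("growth_increment must be named by zone; valid zones: ",
         paste(ZONE_ORDER, collapse = ", "), call. = FALSE)
  }
  if (any(growth_increment < -1e-12)) {
    stop("growth increments must be non-negative", call. = FALSE)
  }
  h <- diff(mesh$y_lines)
  for (zname in names(growth_increment)) {
    inc <- growth_increment[[zname]]
    if (inc == 0) next
    z <- match(zname, ZONE_ORDER)
    rows <- mesh$row_zone == z
    tz <- sum(h[rows])
    if (tz <= 0) {
      stop("cannot grow degenerate zone '", zname, "'", call. = FALSE)
    }
    h[rows] <- h[rows] * (tz + inc) / tz
    mesh$zones$thickness[mesh$zones$zone == zname] <-
      mesh$zones$thickness[mesh$zones$zone == zname] + inc
  }
  if (any(h <= 0)) {
    stop("geometry update produced a non-positive element height ",
         "(inverted element)", call. = FALSE)
  }
  mesh$y_lines <- cumsum(c(mesh$y_lines[1], h))
  .mesh_rebuild_nodes(mesh)
}

#' Total mesh height
#' @param mesh A `gp_mesh`.
#' @return Height of the domain, um.
#' @export
mesh_height <- function(mesh) {
  mesh$y_lines[length(mesh$y_lines)] - mesh$y_lines[1]
}

#' Element Jacobian determinants
#'
#' Determinant of the isoparametric map at each element centroid; all must
#' be positive for a valid (non-inverted) mesh.
#'
#' @param mesh A `gp_mesh`.
#' @return Numeric vector, one determinant per element (um^2 / 4).
#' @export
element_jacobians <- function(mesh) {
  dN <- matrix(c(-1, 1, 1, -1,
                 -1, -1, 1, 1), 2, 4, byrow = TRUE) / 4
  apply(mesh$elems, 1, function(en) {
    J <- dN %*% mesh$nodes[en, ]
    J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  })
}

#' @export
print.gp_mesh <- function(x, ...) {
  cat(sprintf("Structured quad mesh: %d x %d elements (%d nodes), height %.2f um\n",
              x$nx, x$ny, nrow(x$nodes), mesh_height(x)))
  rows <- table(factor(ZONE_ORDER[x$row_zone], levels = ZONE_ORDER))
  cat("  element rows per zone:",
      paste(sprintf("%s=%d", names(rows), rows), collapse = ", "), "\n")
  invisible(x)
}
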