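# Small-strain plane-strain linear elasticity on 4-node quadrilaterals:
# element stiffness (2x2 Gauss), sparse assembly, Dirichlet/traction
# boundary conditions, solve, and centroid stress recovery.
# The elastic solution is used only to recover the axial stress sigma_n that
# drives the growth kinetics; it is never added to the growth-driven
# geometry update (growth and elastic deformation are kept separate, since
# under sustained constant load re-adding elastic displacement every step
# would ratchet).

plane_strain_D <- function(E, nu) {
  E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0,
             nu, 1 - nu, 0,
             0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
}

# d(N_i)/d(xi, eta) for the bilinear quad, nodes ordered ccw from (-1,-1).
.quad_dN <- function(xi, eta) {
  matrix(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta),
           -(1 - xi), -(1 + xi), (1 + xi), (1 - xi)),
         2, 4, byrow = TRUE) / 4
}

.quad_B <- function(dNxy) {
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNxy[1, ]
  B[2, seq(2, 8, 2)] <- dNxy[2, ]
  B[3, seq(1, 8, 2)] <- dNxy[2, ]
  B[3, seq(2, 8, 2)] <- dNxy[1, ]
  B
}

#' Plane-strain stiffness matrix of a 4-node quadrilateral
#'
#' Standard isoparametric bilinear quadrilateral with full 2x2 Gauss
#' integration and the plane-strain constitutive matrix
#' `E/((1+nu)(1-2nu)) * [[1-nu, nu, 0], [nu, 1-nu, 0], [0, 0, (1-2nu)/2]]`.
#' Degrees of freedom are ordered `(u1x, u1y, ..., u4x, u4y)` with nodes
#' counter-clockwise.
#'
#' @param coords 4x2 matrix of node coordinates (um), counter-clockwise.
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return Symmetric 8x8 stiffness matrix (MPa, unit thickness).
#' @export
element_stiffness <- function(coords, E, nu) {
  stopifnot(is.matrix(coords), all(dim(coords) == c(4, 2)),
            E > 0, nu >= 0, nu < 0.5)
  D <- plane_strain_D(E, nu)
  K <- matrix(0, 8, 8)
  g <- 1 / sqrt(3)
  for (xi in c(-g, g)) {
    for (eta in c(-g, g)) {
      dN <- .quad_dN(xi, eta)
      J <- dN %*% coords
      detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (detJ <= 0) {
        stop("inverted element: non-positive Jacobian at a quadrature point",
             call. = FALSE)
      }
      B <- .quad_B(solve(J, dN))
      K <- K + crossprod(B, D %*% B) * detJ
    }
  }
  (K + t(K)) / 2
}

#' Boundary conditions for the growth-plate column
#'
#' Builds the support set and top-edge traction.  Two support layouts:
#'
#' * `"confined"` (default): the metaphyseal (bottom) edge rests on rollers
#'   (`u_y = 0`) and both lateral edges on vertical rollers (`u_x = 0`), as
#'   for a column confined by surrounding tissue.  A uniform axial traction
#'   on the top edge then produces `sigma_n` exactly equal to the applied
#'   stress in every element, whatever the layer stiffnesses — the property
#'   that lets a single stress difference parameterise the kinetics.
#' * `"simple"`: bottom edge `u_y = 0`, bottom-left corner also `u_x = 0`,
#'   lateral edges free (minimal statically determinate support).
#'
#' Additional prescribed displacements can be supplied via `fixed`.
#'
#' @param mesh A `gp_mesh`.
#' @param traction Uniform axial traction on the top (epiphyseal) edge,
#'   MPa, tension positive.
#' @param support `"confined"` or `"simple"`.
#' @param fixed Optional data frame with columns `node`, `dof` (1 = x,
#'   2 = y) and `value` (um) of extra prescribed displacements.
#' @return An object of class `gp_bc`.
#' @export
boundary_conditions <- function(mesh, traction = 0,
                                support = c("confined", "simple"),
                                fixed = NULL) {
  stopifnot(inherits(mesh, "gp_mesh"))
  support <- match.arg(support)
  nx <- mesh$nx; ny <- mesh$ny
  bottom <- seq_len(nx + 1)
  top <- ny * (nx + 1) + seq_len(nx + 1)
  left <- seq(1, (ny + 1) * (nx + 1), by = nx + 1)
  right <- seq(nx + 1, (ny + 1) * (nx + 1), by = nx + 1)
  fx <- data.frame(node = bottom, dof = 2L, value = 0)
  if (support == "confined") {
    fx <- rbind(fx, data.frame(node = c(left, right), dof = 1L, value = 0))
  } else {
    fx <- rbind(fx, data.frame(node = bottom[1], dof = 1L, value = 0))
  }
  if (!is.null(fixed)) {
    stopifnot(all(c("node", "dof", "value") %in% names(fixed)))
    fx <- rbind(fx, fixed[, c("node", "dof", "value")])
  }
  fx <- fx[!duplicated(fx[, c("node", "dof")]), ]
  structure(list(fixed = fx, traction = traction, top_nodes = top,
                 support = support),
            class = "gp_bc")
}

#' Assemble and solve the elasticity problem
#'
#' Assembles the global sparse stiffness matrix from per-element
#' plane-strain stiffnesses, applies consistent nodal loads for the uniform
#' top-edge traction, eliminates prescribed displacements, solves the
#' reduced symmetric positive-definite system, and recovers the stress
#' tensor at each element centroid.
#'
#' Axis-aligned rectangular elements with identical size and material share
#' one cached stiffness, so structured meshes assemble in O(distinct rows).
#'
#' @param mesh A `gp_mesh`.
#' @param bc A [boundary_conditions()] object.
#' @param materials Data frame mapping `tissue` to `youngs_modulus_mpa` and
#'   `poisson_ratio`; defaults to [gp_tissues()].
#' @param n Growth direction for the axial stress, default `(0, 1)`.
#' @return An object of class `gp_fe_solution`: nodal displacements `U`
#'   (um), per-element centroid `stress` (columns `sxx`, `syy`, `sxy`,
#'   MPa), per-element axial stress `sigma_n`, reactions at the fixed
#'   degrees of freedom, and the total applied force.
#' @export
assemble_and_solve <- function(mesh, bc, materials = gp_tissues(),
                               n = c(0, 1)) {
  stopifnot(inherits(mesh, "gp_mesh"), inherits(bc, "gp_bc"))
  im <- match(mesh$elem_tissue, materials$tissue)
  if (anyNA(im)) {
    stop("mesh references tissues missing from the materials table: ",
         paste(unique(mesh$elem_tissue[is.na(im)]), collapse = ", "),
         call. = FALSE)
  }
  E_e <- materials$youngs_modulus_mpa[im]
  nu_e <- materials$poisson_ratio[im]
  ne <- nrow(mesh$elems)
  ndof <- 2L * nrow(mesh$nodes)

  # element dof indices, 8 per element
  edof <- matrix(0L, ne, 8)
  edof[, seq(1, 8, 2)] <- 2L * mesh$elems - 1L
  edof[, seq(2, 8, 2)] <- 2L * mesh$elems

  cache <- new.env(parent = emptyenv())
  Ke_of <- function(e) {
    co <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    dx <- co[2, 1] - co[1, 1]; dy <- co[4, 2] - co[1, 2]
    rect <- abs(co[1, 2] - co[2, 2]) < 1e-12 &&
      abs(co[1, 1] - co[4, 1]) < 1e-12 &&
      abs(co[3, 1] - co[2, 1]) < 1e-12 && abs(co[3, 2] - co[4, 2]) < 1e-12
    if (rect) {
      key <- sprintf("%.12g_%.12g_%g_%g", dx, dy, E_e[e], nu_e[e])
      K <- cache[[key]]
      if (is.null(K)) {
        K <- element_stiffness(co, E_e[e], nu_e[e])
        cache[[key]] <- K
      }
      K
    } else {
      element_stiffness(co, E_e[e], nu_e[e])
    }
  }

  ii <- matrix(0L, 64, ne); jj <- matrix(0L, 64, ne); xx <- matrix(0, 64, ne)
  for (e in seq_len(ne)) {
    K <- Ke_of(e)
    d <- edof[e, ]
    ii[, e] <- rep(d, times = 8)
    jj[, e] <- rep(d, each = 8)
    xx[, e] <- as.numeric(K)
  }
  Kg <- Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj),
                             x = as.numeric(xx), dims = c(ndof, ndof))

  # consistent nodal loads for uniform traction on the top edge
  f <- numeric(ndof)
  if (bc$traction != 0) {
    w <- diff(mesh$x_lines)                      # top-edge segment widths
    tn <- bc$top_nodes
    for (s in seq_along(w)) {
      f[2L * tn[s]] <- f[2L * tn[s]] + bc$traction * w[s] / 2
      f[2L * tn[s + 1]] <- f[2L * tn[s + 1]] + bc$traction * w[s] / 2
    }
  }

  fixed_dof <- 2L * (bc$fixed$node - 1L) + bc$fixed$dof
  if (length(fixed_dof) < 3) {
    stop("boundary conditions leave rigid-body modes unconstrained ",
         "(need at least 3 independent constraints in 2-D)", call. = FALSE)
  }
  u <- numeric(ndof)
  u[fixed_dof] <- bc$fixed$value
  free <- setdiff(seq_len(ndof), fixed_dof)
  rhs <- f[free] - as.numeric(Kg[free, fixed_dof, drop = FALSE] %*%
                                u[fixed_dof])
  u[free] <- tryCatch(
    as.numeric(Matrix::solve(Kg[free, free], rhs)),
    error = function(e) {
      stop("singular stiffness system: boundary conditions leave ",
           "unconstrained modes (", conditionMessage(e), ")", call. = FALSE)
    })

  # centroid stress recovery
  dN0 <- .quad_dN(0, 0)
  stress <- matrix(0, ne, 3, dimnames = list(NULL, c("sxx", "syy", "sxy")))
  for (e in seq_len(ne)) {
    co <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    J <- dN0 %*% co
    B <- .quad_B(solve(J, dN0))
    eps <- B %*% u[edof[e, ]]
    stress[e, ] <- as.numeric(plane_strain_D(E_e[e], nu_e[e]) %*% eps)
  }

  reactions <- as.numeric(Kg %*% u - f)[fixed_dof]
  sol <- structure(list(
    U = matrix(u, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("ux", "uy"))),
    stress = stress,
    sigma_n = NULL,
    reactions = data.frame(dof = fixed_dof, value = reactions),
    applied_force = bc$traction * (max(mesh$x_lines) - min(mesh$x_lines)),
    bc = bc, mesh = mesh),
    class = "gp_fe_solution")
  sol$sigma_n <- axial_stress(sol, n)
  sol
}

#' Axial stress in the growth direction
#'
#' Projects each element's centroid stress tensor onto the growth
#' direction: `sigma_n = n . sigma . n`.
#'
#' @param solution A `gp_fe_solution`.
#' @param n Unit direction (2-vector, normalised internally).
#' @return Numeric vector, one `sigma_n` (MPa) per element.
#' @export
axial_stress <- function(solution, n = c(0, 1)) {
  stopifnot(inherits(solution, "gp_fe_solution"))
  n <- n / sqrt(sum(n^2))
  s <- solution$stress
  n[1]^2 * s[, "sxx"] + n[2]^2 * s[, "syy"] + 2 * n[1] * n[2] * s[, "sxy"]
}

#' @export
print.gp_fe_solution <- function(x, ...) {
  cat(sprintf("Plane-strain FE solution: %d nodes, %d elements\n",
              nrow(x$U), nrow(x$stress)))
  cat(sprintf("  traction %.4g MPa (%s support); sigma_n range [%.6g, %.6g] MPa\n",
              x$bc$traction, x$bc$support, min(x$sigma_n), max(x$sigma_n)))
  invisible(x)
}
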