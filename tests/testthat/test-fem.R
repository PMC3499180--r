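# Plane-strain FE layer: element stiffness, patch tests, layered-column
# stress transmission, equilibrium.

test_that("element stiffness is symmetric, rank 5 and scale invariant", {
  co <- rbind(c(0, 0), c(40, 0), c(40, 27), c(0, 27))
  K <- element_stiffness(co, E = 0.27, nu = 0.13)
  expect_lt(norm(K - t(K), "F"), 1e-12 * norm(K, "F"))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10 * max(ev)), 3)  # 3 rigid-body modes
  expect_true(all(ev > -1e-10 * max(ev)))          # positive semi-definite
  # 2-D plane-strain stiffness is invariant under uniform scaling
  expect_equal(element_stiffness(2 * co, 0.27, 0.13), K, tolerance = 1e-12)
  # skewed but valid element still SPD on the constrained space
  co_skew <- rbind(c(0, 0), c(40, 5), c(45, 30), c(-2, 26))
  Ks <- element_stiffness(co_skew, 2000, 0.3)
  expect_lt(norm(Ks - t(Ks), "F"), 1e-12 * norm(Ks, "F"))
  # inverted element rejected
  expect_error(element_stiffness(co[c(1, 4, 3, 2), ], 1, 0.3), "inverted")
})

test_that("uniform traction on a homogeneous block passes the patch test", {
  m <- baseline_mesh()
  mat <- uniform_materials(E = 2000, nu = 0.3)
  for (support in c("confined", "simple")) {
    bc <- boundary_conditions(m, traction = -0.2, support = support)
    sol <- assemble_and_solve(m, bc, materials = mat)
    expect_lt(max(abs(sol$stress[, "syy"] + 0.2)), 1e-8)
    expect_lt(max(abs(sol$stress[, "sxy"])), 1e-8)
  }
  # closed-form top displacement, laterally confined column:
  # u_y = sigma (1+nu)(1-2nu) / (E (1-nu)) * H
  sol_c <- assemble_and_solve(m, boundary_conditions(m, -0.2, "confined"),
                              materials = mat)
  uy_top <- sol_c$U[sol_c$bc$top_nodes, "uy"]
  uy_exact <- -0.2 * (1 + 0.3) * (1 - 2 * 0.3) / (2000 * (1 - 0.3)) * 800
  expect_equal(max(abs(uy_top - uy_exact)) / abs(uy_exact), 0,
               tolerance = 1e-8)
  # laterally free column: u_y = sigma (1 - nu^2) / E * H
  sol_s <- assemble_and_solve(m, boundary_conditions(m, -0.2, "simple"),
                              materials = mat)
  uy_free <- -0.2 * (1 - 0.3^2) / 2000 * 800
  expect_equal(max(abs(sol_s$U[sol_s$bc$top_nodes, "uy"] - uy_free)) /
                 abs(uy_free), 0, tolerance = 1e-8)
  # zero traction, zero displacement
  sol0 <- assemble_and_solve(m, boundary_conditions(m, 0), materials = mat)
  expect_equal(max(abs(sol0$U)), 0)
})

test_that("linear Dirichlet data reproduces constant stress (patch test)", {
  m <- baseline_mesh()
  mat <- uniform_materials(E = 10, nu = 0.25)
  # prescribe u = (a x, b y) on the whole boundary, solve the interior
  a <- 1e-3; b <- -2e-3
  nx <- m$nx; ny <- m$ny
  onb <- which(m$nodes[, 1] %in% range(m$x_lines) |
                 m$nodes[, 2] %in% range(m$y_lines))
  fixed <- rbind(
    data.frame(node = onb, dof = 1L, value = a * m$nodes[onb, 1]),
    data.frame(node = onb, dof = 2L, value = b * m$nodes[onb, 2]))
  bc <- boundary_conditions(m, traction = 0, fixed = fixed)
  bc$fixed <- fixed  # only the prescribed linear field, no extra supports
  sol <- assemble_and_solve(m, bc, materials = mat)
  D <- growthplate:::plane_strain_D(10, 0.25)
  s_exact <- as.numeric(D %*% c(a, b, 0))
  expect_lt(max(abs(sol$stress[, "sxx"] - s_exact[1])), 1e-8)
  expect_lt(max(abs(sol$stress[, "syy"] - s_exact[2])), 1e-8)
  expect_lt(max(abs(sol$stress[, "sxy"])), 1e-8)
  # and the interior displacement is the linear field itself
  expect_equal(sol$U[, "ux"], a * m$nodes[, 1], tolerance = 1e-10)
})

test_that("layered five-region column transmits the applied axial stress", {
  for (load in c(-0.2, 0.1)) {
    m <- baseline_mesh(load = load)
    sol <- assemble_and_solve(m, boundary_conditions(m, traction = load))
    expect_lt(max(abs(sol$sigma_n - load)), 1e-6)
    # tissue-mapped materials: cartilage is orders softer, so almost the
    # whole axial compliance sits in the growth plate
    expect_equal(axial_stress(sol, c(0, 1)), sol$sigma_n)
  }
  # refinement keeps the transmitted stress at machine level
  m2 <- baseline_mesh(load = -0.2, lateral_per_column = 2, bone_rows = 4)
  sol2 <- assemble_and_solve(m2, boundary_conditions(m2, traction = -0.2))
  expect_lt(max(abs(sol2$sigma_n + 0.2)), 1e-6)
})

test_that("reactions balance the applied traction", {
  for (support in c("confined", "simple")) {
    m <- baseline_mesh()
    bc <- boundary_conditions(m, traction = 0.1, support = support)
    sol <- assemble_and_solve(m, bc)
    ydofs <- sol$reactions$dof %% 2 == 0
    resid <- sum(sol$reactions$value[ydofs]) + sol$applied_force
    expect_lt(abs(resid) / abs(sol$applied_force), 1e-8)
  }
})

test_that("rigid-body motion produces zero stress and bad supports error", {
  m <- baseline_mesh()
  # pure translation prescribed on the whole boundary
  onb <- which(m$nodes[, 1] %in% range(m$x_lines) |
                 m$nodes[, 2] %in% range(m$y_lines))
  fixed <- rbind(data.frame(node = onb, dof = 1L, value = 3),
                 data.frame(node = onb, dof = 2L, value = -2))
  bc <- boundary_conditions(m, traction = 0, fixed = fixed)
  bc$fixed <- fixed
  sol <- assemble_and_solve(m, bc)
  expect_lt(max(abs(sol$stress)), 1e-9)
  # under-constrained problem is rejected
  bc2 <- boundary_conditions(m, traction = 0.1)
  bc2$fixed <- bc2$fixed[1:2, ]
  expect_error(assemble_and_solve(m, bc2), "singular|unconstrained")
})
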