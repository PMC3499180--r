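# Cell-level growth laws: stress modulation of hypertrophic cell height,
# maturation kinetics, strain-rate tensors and their steady-state identity.

test_that("stress difference is the offset from the physiological baseline", {
  expect_equal(stress_difference(-0.2, 0), -0.2)
  expect_equal(stress_difference(0.05, -0.05), 0.10)
  for (s in c(-1, 0, 0.3)) expect_equal(stress_difference(s, s), 0)
})

test_that("calibrated height-change branches reproduce the measured heights", {
  expect_equal(d_hmax(0.1), 0.035)
  expect_equal(d_hmax(0), 0)
  # middle branch: +0.27|dsn| is forced by the measured 35.94 um at -0.1 MPa
  expect_equal(d_hmax(-0.1), 0.027)
  # steep branch forced by 34.30 um at -0.2 MPa: 34.30/35 - 1 = -0.020
  expect_equal(d_hmax(-0.2), -0.020)
  # h_max reproduces all four tabulated heights to 0.01 um
  tab <- gp_load_cases()
  expect_true(all(abs(max_hypertrophic_height(tab$delta_sigma_n, 35) -
                        tab$h_max_um) <= 0.01))
})

test_that("iteration interval reproduces the tabulated values to 0.001 days", {
  tab <- gp_load_cases()
  dt <- time_step(max_hypertrophic_height(tab$delta_sigma_n, 35),
                  tab$g_stokes_um_day)
  expect_true(all(abs(dt - tab$delta_t_days) <= 0.001))
  expect_equal(time_step(36.22, 228.7), 0.158, tolerance = 0.001 / 0.158)
  expect_equal(time_step(5, 5), 1)
  expect_error(time_step(35, 0), "positive")
  expect_error(time_step(35, -1), "positive")
})

test_that("maturation law is a bounded monotone ramp from h_p to h_max", {
  expect_equal(chondrocyte_height(12, 36, 0, 2), 12)
  expect_equal(chondrocyte_height(12, 36, 2, 2), 36)
  expect_equal(chondrocyte_height(12, 36, 1, 2), 24)  # linear midpoint
  ages <- seq(0, 0.966, length.out = 25)
  h <- chondrocyte_height(12, 35, ages, 0.966)
  expect_true(all(diff(h) >= 0))
  expect_true(all(h >= 12 & h <= 35))
  expect_error(chondrocyte_height(12, 36, -0.1, 2), "maturation_age")
  expect_error(chondrocyte_height(12, 36, 2.5, 2), "maturation_age")
})

test_that("growth rate is the proliferation-hypertrophy product", {
  expect_equal(growth_rate(0, 35), 0)
  # table round-trips through delta_t inversion (rounded delta_t explains
  # the ~0.2% residual)
  expect_equal(growth_rate(1 / 0.161, 35.00), 217.0, tolerance = 0.002)
  expect_equal(growth_rate(1 / 0.158, 36.22), 228.7, tolerance = 0.003)
})

test_that("proliferation strain rate is rank one along the growth direction", {
  d <- proliferation_strain_rate(6.211, 12, 264, c(0, 1))
  expect_equal(d$nn, 6.211 * 12 / 264)
  expect_equal(d$nn, 0.2823, tolerance = 2e-4)
  expect_equal(d$tensor[1, 1], 0)
  expect_equal(d$tensor[1, 2], 0)
  expect_equal(d$tensor[2, 2], d$nn)
  expect_equal(proliferation_strain_rate(0, 12, 264)$tensor,
               matrix(0, 2, 2))
})

test_that("hypertrophy strain rate sums per-cell elongation rates", {
  # single cell 5 um above h_p after half a day in a 162 um zone
  col <- chondrocyte_column(22, ages = 0.5, heights = 17)
  d <- hypertrophy_strain_rate(col, h_p = 12, l_h = 162)
  expect_equal(d$nn, 10 / 162)
  # cells still at h_p contribute nothing
  col0 <- chondrocyte_column(22, ages = c(0.2, 0.4), heights = c(12, 12))
  expect_equal(hypertrophy_strain_rate(col0, 12, 162)$nn, 0)
  # zero age with height above h_p is a modelling violation
  bad <- chondrocyte_column(22, ages = c(0, 0.4), heights = c(13, 14))
  expect_error(hypertrophy_strain_rate(bad, 12, 162), "zero maturation age")
  # steady-state column: explicit summation equals the closed form
  k <- kinetic_closure(0)
  col_ss <- steady_state_column(k$lc$cells[["proliferative"]],
                                k$lc$cells[["hypertrophic"]],
                                k$lc$delta_t, k$h_p, k$lc$h_max)
  manual <- sum((col_ss$hypertrophic$height - k$h_p) /
                  col_ss$hypertrophic$age) / k$l_h
  closed <- k$lc$cells[["hypertrophic"]] * (k$lc$h_max - k$h_p) /
    (k$t_E * k$l_h)
  d_ss <- hypertrophy_strain_rate(col_ss, k$h_p, k$l_h)
  expect_equal(d_ss$nn, manual)
  expect_equal(d_ss$nn, closed, tolerance = 1e-12)
})

test_that("growth tensor adds contributions sharing a direction", {
  z <- proliferation_strain_rate(0, 12, 264)
  d <- proliferation_strain_rate(6, 12, 264)
  expect_equal(growth_tensor(z, z)$tensor, matrix(0, 2, 2))
  expect_equal(growth_tensor(d, z)$tensor, d$tensor)
  dx <- proliferation_strain_rate(6, 12, 264, n = c(1, 0))
  expect_error(growth_tensor(d, dx), "different growth directions")
})

test_that("steady-state master identity: zone-weighted strain rates give G", {
  for (load in tabulated_loads()) {
    k <- kinetic_closure(load)
    col <- steady_state_column(k$lc$cells[["proliferative"]],
                               k$lc$cells[["hypertrophic"]],
                               k$lc$delta_t, k$h_p, k$lc$h_max)
    d_p <- proliferation_strain_rate(k$n_p, k$h_p, k$l_p)
    d_h <- hypertrophy_strain_rate(col, k$h_p, k$l_h)
    lhs <- k$l_p * d_p$nn + k$l_h * d_h$nn
    rhs <- growth_rate(k$n_p, k$lc$h_max)
    expect_lt(abs(lhs - rhs) / rhs, 1e-10)
  }
})

test_that("growth rate increases monotonically with the applied stress", {
  tab <- gp_load_cases()
  o <- order(tab$delta_sigma_n)
  g <- (tab$h_max_um / tab$delta_t_days)[o]
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(tab$g_stokes_um_day[o]) > 0))
})

test_that("distribution tensor supports only the isotropic columnar case", {
  expect_equal(distribution_tensor(cell_distribution(1)), diag(2))
  expect_equal(distribution_tensor(cell_distribution(1, concentration = 3)),
               3 * diag(2))
  expect_error(distribution_tensor(cell_distribution(2)), "r = 1")
})

test_that("column conveyor preserves counts and steady ages", {
  k <- kinetic_closure(0)
  col <- steady_state_column(22, 6, k$lc$delta_t, k$h_p, k$lc$h_max)
  adv <- growthplate:::advance_column(col, k$lc$delta_t, k$t_E,
                                      k$h_p, k$lc$h_max)
  expect_equal(nrow(adv$hypertrophic), 6)
  expect_equal(adv$proliferative_count, 22L)
  # a full-interval advance returns the same steady age ladder
  expect_equal(adv$hypertrophic$age, col$hypertrophic$age)
  expect_equal(adv$hypertrophic$height, col$hypertrophic$height)
  expect_error(chondrocyte_column(22, c(0.1, 0.2), c(15, 13)),
               "non-decreasing")
})
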