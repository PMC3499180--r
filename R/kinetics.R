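# Cell-level growth kinetics: the growth rate G = n_p * h_max, the stress
# modulation of the maximum hypertrophic cell height, the maturation law for
# hypertrophying chondrocytes, and the rank-one strain-rate tensors that
# carry proliferation and hypertrophy into the continuum.

#' Stress difference driving mechanical modulation
#'
#' The kinetics respond to the difference between the actual axial stress in
#' the growth direction and the physiological baseline; under physiological
#' loading the difference is zero and growth proceeds at its baseline rate.
#'
#' @param sigma_n Actual axial stress in the growth direction, MPa
#'   (tension positive).
#' @param sigma_n_f Physiological baseline stress, MPa (default 0).
#' @return `sigma_n - sigma_n_f`, MPa.
#' @export
stress_difference <- function(sigma_n, sigma_n_f = gp_constants()$sigma_n_f) {
  sigma_n - sigma_n_f
}

#' Fractional change of the maximum hypertrophic cell height under load
#'
#' Piecewise-linear response of the terminal hypertrophic chondrocyte height
#' to a sustained axial stress difference, calibrated against experimental
#' size-change measurements in the rat proximal tibia.  Writing `a = |dsn|`:
#'
#' * `dsn >= 0` (tension):          `D = 0.35 a`  (taller terminal cells)
#' * `-0.1 <= dsn < 0` MPa:         `D = 0.27 a`  (mild compression still
#'   increases terminal height while the growth rate falls through reduced
#'   zone widths and cell numbers)
#' * `dsn < -0.1` MPa:              `D = -0.47 a + 0.074` (stronger
#'   compression finally shrinks the terminal cells)
#'
#' The non-monotone middle branch is what the measured heights
#' (36.22, 35.00, 35.94, 34.30 um at +0.1, 0.0, -0.1, -0.2 MPa) force; see
#' the package vignette for the calibration.
#'
#' @param delta_sigma_n Stress difference, MPa (vectorised).
#' @return Dimensionless fractional height change.
#' @seealso [max_hypertrophic_height()]
#' @export
#' @examples
#' d_hmax(c(0.1, 0, -0.1, -0.2))
d_hmax <- function(delta_sigma_n) {
  a <- abs(delta_sigma_n)
  ifelse(delta_sigma_n >= 0, 0.35 * a,
         ifelse(delta_sigma_n >= -0.1, 0.27 * a, -0.47 * a + 0.074))
}

#' Maximum hypertrophic chondrocyte height under sustained load
#'
#' `h_max = (1 + D(delta_sigma_n)) * h_max_f`, where `D` is the calibrated
#' fractional height change ([d_hmax()]) and `h_max_f` the physiological
#' terminal height (35 um in the rat proximal tibia).
#'
#' @param delta_sigma_n Stress difference, MPa (vectorised).
#' @param h_max_f Physiological maximum height, um.
#' @return `h_max` in um.
#' @export
#' @examples
#' max_hypertrophic_height(0.1, 35)   # 36.22 um (to 2 decimals)
max_hypertrophic_height <- function(delta_sigma_n,
                                    h_max_f = gp_constants()$h_max_f) {
  stopifnot(h_max_f > 0)
  (1 + d_hmax(delta_sigma_n)) * h_max_f
}

#' Height of a hypertrophying chondrocyte during maturation
#'
#' A chondrocyte leaving the proliferative zone enlarges linearly from the
#' proliferative height `h_p` to the terminal height `h_max` over the
#' maturation time `t_E`:
#' `h_i(age) = h_p + (h_max - h_p) * age / t_E`.
#'
#' @param h_p Proliferative cell height, um.
#' @param h_max Terminal hypertrophic height, um.
#' @param maturation_age Time since hypertrophy onset, days (vectorised).
#' @param t_E Full maturation time, days.
#' @return Cell height(s), um.
#' @export
chondrocyte_height <- function(h_p, h_max, maturation_age, t_E) {
  stopifnot(h_p > 0, h_max >= h_p, t_E > 0)
  if (any(maturation_age < -1e-12) || any(maturation_age > t_E + 1e-9)) {
    stop("maturation_age must lie in [0, t_E]: a cell outside that window ",
         "is either not yet hypertrophic or already fully mature",
         call. = FALSE)
  }
  h_p + (h_max - h_p) * pmin(pmax(maturation_age, 0), t_E) / t_E
}

#' Longitudinal growth rate from cell kinetics
#'
#' In steady state every proliferated chondrocyte completes maturation and,
#' with no extracellular matrix separating hypertrophic cells along the
#' column, each contributes its terminal height to elongation:
#' `G = n_p * h_max`.
#'
#' @param n_p Proliferation rate, cells/day.
#' @param h_max Terminal hypertrophic height, um.
#' @return Growth rate, um/day.
#' @export
growth_rate <- function(n_p, h_max) {
  stopifnot(all(n_p >= 0), all(h_max > 0))
  n_p * h_max
}

#' Iteration time interval
#'
#' At equilibrium one cell proliferates and one mature hypertrophic cell
#' undergoes apoptosis per interval, so the natural step is the time to grow
#' one terminal cell height: `delta_t = h_max / G`.
#'
#' @param h_max Terminal hypertrophic height, um.
#' @param G Growth rate, um/day.
#' @return Time interval, days.
#' @export
#' @examples
#' time_step(35.00, 217.0)  # ~0.161 days
time_step <- function(h_max, G) {
  stopifnot(h_max > 0)
  if (any(G <= 0)) stop("growth rate G must be positive", call. = FALSE)
  h_max / G
}

# ---- growth-rate tensors ----------------------------------------------------

new_growth_tensor <- function(nn, n) {
  n <- n / sqrt(sum(n^2))
  structure(list(tensor = nn * (n %o% n), nn = nn, n = n),
            class = "gp_growth_tensor")
}

#' @export
print.gp_growth_tensor <- function(x, ...) {
  cat(sprintf("Growth strain-rate tensor (rank one along n = [%.3g, %.3g])\n",
              x$n[1], x$n[2]))
  cat(sprintf("  nn-component: %.6g /day\n", x$nn))
  invisible(x)
}

#' Strain rate due to chondrocyte proliferation
#'
#' Mitosis in the proliferative zone inserts `n_p` cells of height `h_p` per
#' day into a column of width `l_p`, giving the rank-one tensor
#' `(n_p h_p / l_p) n (x) n` along the growth direction `n`.
#'
#' @param n_p Proliferation rate, cells/day.
#' @param h_p Proliferative cell height, um.
#' @param l_p Proliferative zone width, um.
#' @param n Growth direction (2-vector, normalised internally).
#' @return A `gp_growth_tensor` (fields `tensor` 2x2, `nn`, `n`), units 1/day.
#' @export
proliferation_strain_rate <- function(n_p, h_p, l_p, n = c(0, 1)) {
  stopifnot(l_p > 0, n_p >= 0, h_p > 0)
  new_growth_tensor(n_p * h_p / l_p, n)
}

#' Strain rate due to chondrocyte hypertrophy
#'
#' Each maturing cell in the column contributes its elongation rate
#' `(h_i - h_p) / Delta_t_i` (height gained since hypertrophy onset over
#' the time taken to gain it); summed over the column and normalised by the
#' hypertrophic zone width `l_h`:
#' `(1/l_h) * sum_i (h_i - h_p)/Delta_t_i * n (x) n`.
#'
#' @param column A [chondrocyte_column()].
#' @param h_p Proliferative cell height, um.
#' @param l_h Hypertrophic zone width, um.
#' @param n Growth direction (2-vector).
#' @return A `gp_growth_tensor`, units 1/day.
#' @export
hypertrophy_strain_rate <- function(column, h_p, l_h, n = c(0, 1)) {
  stopifnot(inherits(column, "gp_chondrocyte_column"), l_h > 0)
  age <- column$hypertrophic$age
  h <- column$hypertrophic$height
  if (length(age) == 0) return(new_growth_tensor(0, n))
  if (any(age <= 0 & h > h_p + 1e-12)) {
    stop("hypertrophic cell with zero maturation age but height above h_p: ",
         "elongation rate undefined", call. = FALSE)
  }
  if (any(age <= 0)) {
    # cells exactly at onset have gained no height and contribute nothing
    keep <- age > 0
    age <- age[keep]; h <- h[keep]
  }
  new_growth_tensor(sum((h - h_p) / age) / l_h, n)
}

#' Total growth-rate tensor
#'
#' The growth strain rate is the sum of the proliferative and hypertrophic
#' contributions; both must share the same growth direction.
#'
#' @param d_prolif,d_hyper `gp_growth_tensor` objects.
#' @return Their componentwise sum, a `gp_growth_tensor`.
#' @export
growth_tensor <- function(d_prolif, d_hyper) {
  stopifnot(inherits(d_prolif, "gp_growth_tensor"),
            inherits(d_hyper, "gp_growth_tensor"))
  if (max(abs(d_prolif$n - d_hyper$n)) > 1e-9) {
    stop("proliferation and hypertrophy tensors have different growth ",
         "directions", call. = FALSE)
  }
  new_growth_tensor(d_prolif$nn + d_hyper$nn, d_prolif$n)
}

#' Chondrocyte distribution descriptor
#'
#' Bookkeeping for cell concentration and columnar anisotropy in a cartilage
#' zone: the ratio `r` of cells along the growth direction to cells in the
#' orthogonal direction, and (optionally) a concentration.
#'
#' @param anisotropy_ratio Cells-along-n to cells-across ratio (`r`); the
#'   parameterised mesh ties one element to one cell so `r = 1` throughout.
#' @param concentration Cells per volume, or `NULL` if unknown.
#' @param n Growth direction (2-vector).
#' @return An object of class `gp_cell_distribution`.
#' @export
cell_distribution <- function(anisotropy_ratio = 1, concentration = NULL,
                              n = c(0, 1)) {
  stopifnot(anisotropy_ratio > 0)
  n <- n / sqrt(sum(n^2))
  structure(list(anisotropy_ratio = anisotropy_ratio,
                 concentration = concentration, n = n),
            class = "gp_cell_distribution")
}

#' Distribution tensor of a cartilage zone
#'
#' For the isotropic case `r = 1` (one element per cell, as the mesh is
#' built) the transversely isotropic distribution tensor degenerates to the
#' identity, scaled by the concentration when one is supplied.  The general
#' anisotropic form is not implemented: its published statement is
#' typographically ambiguous, and no simulated condition requires it.
#'
#' @param dist A [cell_distribution()].
#' @return A 2x2 matrix.
#' @export
distribution_tensor <- function(dist) {
  stopifnot(inherits(dist, "gp_cell_distribution"))
  if (abs(dist$anisotropy_ratio - 1) > 1e-12) {
    stop("distribution tensors are only implemented for anisotropy ratio ",
         "r = 1: the published transversely isotropic form is ambiguous ",
         "for r != 1 and is not exercised by any supported load case",
         call. = FALSE)
  }
  s <- if (is.null(dist$concentration)) 1 else dist$concentration
  s * diag(2)
}

# ---- chondrocyte columns ----------------------------------------------------

#' A chondrocyte column
#'
#' State of one cell column of the growth plate: the number of proliferative
#' cells and, for each hypertrophying cell, its maturation age and height.
#' Cells are ordered by increasing age (youngest nearest the proliferative
#' border); heights must be non-decreasing with age.
#'
#' @param proliferative_count Number of proliferative cells.
#' @param ages Maturation ages of the hypertrophic cells, days.
#' @param heights Matching cell heights, um.
#' @return An object of class `gp_chondrocyte_column`.
#' @seealso [steady_state_column()]
#' @export
chondrocyte_column <- function(proliferative_count, ages = numeric(),
                               heights = numeric()) {
  stopifnot(proliferative_count >= 0, length(ages) == length(heights))
  o <- order(ages)
  ages <- ages[o]; heights <- heights[o]
  if (length(heights) > 1 && any(diff(heights) < -1e-9)) {
    stop("cell heights must be non-decreasing with maturation age",
         call. = FALSE)
  }
  structure(list(proliferative_count = as.integer(proliferative_count),
                 hypertrophic = data.frame(age = ages, height = heights)),
            class = "gp_chondrocyte_column")
}

#' Seed a column at kinetic steady state
#'
#' Hypertrophic cells are staggered one iteration apart: the i-th cell
#' (1-based from the proliferative border) has maturation age `i * delta_t`
#' and the height the linear maturation law assigns to that age, with
#' `t_E = n_hyper * delta_t` so the oldest cell is exactly mature.
#'
#' @param n_prolif,n_hyper Cells per column in each zone.
#' @param delta_t Iteration interval, days.
#' @param h_p Proliferative cell height, um.
#' @param h_max Terminal hypertrophic height, um.
#' @return A `gp_chondrocyte_column`.
#' @export
steady_state_column <- function(n_prolif, n_hyper, delta_t, h_p, h_max) {
  stopifnot(n_hyper >= 1, delta_t > 0)
  t_E <- n_hyper * delta_t
  ages <- seq_len(n_hyper) * delta_t
  chondrocyte_column(n_prolif, ages,
                     chondrocyte_height(h_p, h_max, ages, t_E))
}

# Advance a column by dt days on the maturation conveyor: ages increase, any
# cell past t_E dies (apoptosis) and is replaced at the young end by a cell
# that entered hypertrophy when the dying one left, preserving the count.
advance_column <- function(column, dt, t_E, h_p, h_max) {
  age <- column$hypertrophic$age + dt
  dead <- age > t_E + 1e-9
  age <- c(age[dead] - t_E, age[!dead])
  chondrocyte_column(column$proliferative_count, age,
                     chondrocyte_height(h_p, h_max, age, t_E))
}
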