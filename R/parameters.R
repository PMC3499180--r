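# Parameter fixtures for the rat proximal tibia: tissue elastic properties,
# per-load-case cartilage zone thicknesses, cells per column, experimental
# growth rates, hypertrophic cell heights and iteration time intervals.
# Shipped as plain-text tables under inst/extdata, one file per table.

.gp_extdata <- function(file) {
  system.file("extdata", file, package = "growthplate", mustWork = TRUE)
}

#' Elastic properties of the growth-plate tissues
#'
#' Linear isotropic elastic constants for the four tissues of the modelled
#' domain: trabecular bone and the reserve, proliferative and hypertrophic
#' cartilage zones.  Cartilage moduli are far softer than bone (0.25-0.48 MPa
#' vs 2000 MPa), which is why the growth plate carries almost all of the
#' axial compliance of the section.
#'
#' @return A data frame with columns `tissue`, `youngs_modulus_mpa`
#'   and `poisson_ratio`.
#' @seealso [get_tissue()]
#' @export
#' @examples
#' gp_tissues()
gp_tissues <- function() {
  read.csv(.gp_extdata("tissue_properties.csv"), stringsAsFactors = FALSE)
}

#' Look up one tissue's elastic properties
#'
#' @param tissue One of `"trabecular_bone"`, `"reserve"`, `"proliferative"`,
#'   `"hypertrophic"`.
#' @return A list with `tissue`, `youngs_modulus` (MPa) and `poisson_ratio`.
#' @export
#' @examples
#' get_tissue("hypertrophic")
get_tissue <- function(tissue) {
  tab <- gp_tissues()
  i <- match(tissue, tab$tissue)
  if (is.na(i)) {
    stop("unknown tissue '", tissue, "'; valid tissues are: ",
         paste(tab$tissue, collapse = ", "), call. = FALSE)
  }
  list(tissue = tab$tissue[i],
       youngs_modulus = tab$youngs_modulus_mpa[i],
       poisson_ratio = tab$poisson_ratio[i])
}

#' Physiological constants of the modelled growth plate
#'
#' Reference values for the unloaded rat proximal tibia: the physiological
#' maximum hypertrophic chondrocyte height `h_max_f` (35 um), the number of
#' chondrocyte columns (20) and their lateral spacing (40 um, so the columns
#' exactly tile the 800 um domain width), the square domain side, the default
#' simulated duration (23 days) and the physiological axial stress baseline
#' `sigma_n_f` (0 MPa, so applied loads are stated directly as the stress
#' difference from physiology).
#'
#' @return A named list.
#' @export
gp_constants <- function() {
  k <- yaml::read_yaml(.gp_extdata("physiological_constants.yaml"))
  list(h_max_f = k$h_max_f_um,
       columns = k$columns,
       column_spacing = k$column_spacing_um,
       domain_side = k$domain_side_um,
       duration = k$duration_days,
       sigma_n_f = k$sigma_n_f_mpa)
}

#' All tabulated load cases
#'
#' The four sustained axial stress differences for which the complete
#' experimental parameter set exists: zone thicknesses, cells per column,
#' the experimentally derived growth rate `G_Stokes`, the maximum
#' hypertrophic cell height `h_max`, and the iteration time interval
#' `delta_t = h_max / G_Stokes`.
#'
#' @return A data frame with one row per load case, ordered from tension
#'   (+0.1 MPa) to the strongest compression (-0.2 MPa).
#' @seealso [get_load_case()]
#' @export
gp_load_cases <- function() {
  th <- read.csv(.gp_extdata("zone_thicknesses.csv"))
  ce <- read.csv(.gp_extdata("cells_per_column.csv"))
  ti <- read.csv(.gp_extdata("time_intervals.csv"))
  out <- ti[, "delta_sigma_n", drop = FALSE]
  m <- function(x) match(round(out$delta_sigma_n, 6), round(x$delta_sigma_n, 6))
  out$reserve_um <- th$reserve_um[m(th)]
  out$proliferative_um <- th$proliferative_um[m(th)]
  out$hypertrophic_um <- th$hypertrophic_um[m(th)]
  out$cells_proliferative <- ce$proliferative[m(ce)]
  out$cells_hypertrophic <- ce$hypertrophic[m(ce)]
  out$g_stokes_um_day <- ti$g_stokes_um_day
  out$h_max_um <- ti$h_max_um
  out$delta_t_days <- ti$delta_t_days
  out
}

#' Retrieve the parameter set for one load case
#'
#' Returns the full parameter row for a sustained axial stress difference:
#' cartilage zone thicknesses (reserve, proliferative, hypertrophic),
#' chondrocyte counts per column, the experimental growth rate, the maximum
#' hypertrophic cell height and the iteration time interval.
#'
#' Only the four tabulated stresses (+0.1, 0.0, -0.1, -0.2 MPa) carry
#' experimental backing.  With `interpolate = TRUE` an intermediate stress
#' in `[-0.2, 0.1]` MPa is accepted: thicknesses, cell counts (rounded to
#' integers) and `G` are interpolated piecewise-linearly between the
#' tabulated cases, while `h_max` comes from its calibrated stress response
#' ([max_hypertrophic_height()]) and `delta_t = h_max / G`.  Interpolated
#' cases are a modelling extrapolation, not validated conditions.
#'
#' @param delta_sigma_n Sustained axial stress difference in MPa, tension
#'   positive.
#' @param interpolate Allow non-tabulated stresses (default `FALSE`).
#' @return An object of class `gp_load_case`: a list with fields
#'   `delta_sigma_n`, `thickness` (named vector, um), `cells` (named
#'   integer vector), `g_stokes` (um/day), `h_max` (um), `delta_t` (days)
#'   and `tabulated` (logical).
#' @export
#' @examples
#' get_load_case(0)
#' get_load_case(-0.2)$delta_t
get_load_case <- function(delta_sigma_n, interpolate = FALSE) {
  stopifnot(is.numeric(delta_sigma_n), length(delta_sigma_n) == 1,
            is.finite(delta_sigma_n))
  tab <- gp_load_cases()
  i <- which(abs(tab$delta_sigma_n - delta_sigma_n) < 1e-9)
  if (length(i) == 1) {
    row <- tab[i, ]
    return(new_load_case(row$delta_sigma_n,
                         c(reserve = row$reserve_um,
                           proliferative = row$proliferative_um,
                           hypertrophic = row$hypertrophic_um),
                         c(proliferative = row$cells_proliferative,
                           hypertrophic = row$cells_hypertrophic),
                         row$g_stokes_um_day, row$h_max_um, row$delta_t_days,
                         tabulated = TRUE))
  }
  if (!interpolate) {
    stop("delta_sigma_n = ", delta_sigma_n, " MPa is not a tabulated load ",
         "case; valid values are ",
         paste(sprintf("%+.1f", tab$delta_sigma_n), collapse = ", "),
         " MPa (or pass interpolate = TRUE)", call. = FALSE)
  }
  rng <- range(tab$delta_sigma_n)
  if (delta_sigma_n < rng[1] || delta_sigma_n > rng[2]) {
    stop("delta_sigma_n = ", delta_sigma_n, " MPa outside the tabulated ",
         "range [", rng[1], ", ", rng[2], "] MPa; extrapolation is not ",
         "supported", call. = FALSE)
  }
  o <- order(tab$delta_sigma_n)
  ix <- function(y) approx(tab$delta_sigma_n[o], y[o], xout = delta_sigma_n)$y
  thick <- c(reserve = ix(tab$reserve_um),
             proliferative = ix(tab$proliferative_um),
             hypertrophic = ix(tab$hypertrophic_um))
  cells <- c(proliferative = as.integer(round(ix(tab$cells_proliferative))),
             hypertrophic = as.integer(round(ix(tab$cells_hypertrophic))))
  g <- ix(tab$g_stokes_um_day)
  h_max <- max_hypertrophic_height(delta_sigma_n, gp_constants()$h_max_f)
  new_load_case(delta_sigma_n, thick, cells, g, h_max, h_max / g,
                tabulated = FALSE)
}

new_load_case <- function(delta_sigma_n, thickness, cells, g_stokes,
                          h_max, delta_t, tabulated) {
  structure(list(delta_sigma_n = delta_sigma_n,
                 thickness = thickness,
                 cells = cells,
                 g_stokes = g_stokes,
                 h_max = h_max,
                 delta_t = delta_t,
                 tabulated = tabulated),
            class = "gp_load_case")
}

#' @export
print.gp_load_case <- function(x, ...) {
  cat(sprintf("Growth-plate load case: delta_sigma_n = %+.3g MPa%s\n",
              x$delta_sigma_n,
              if (x$tabulated) "" else " (interpolated)"))
  cat(sprintf("  zone thickness [um]: reserve %.1f, proliferative %.1f, hypertrophic %.1f\n",
              x$thickness[["reserve"]], x$thickness[["proliferative"]],
              x$thickness[["hypertrophic"]]))
  cat(sprintf("  cells per column: %d proliferative + %d hypertrophic\n",
              x$cells[["proliferative"]], x$cells[["hypertrophic"]]))
  cat(sprintf("  G = %.1f um/day, h_max = %.2f um, delta_t = %.3f days\n",
              x$g_stokes, x$h_max, x$delta_t))
  invisible(x)
}
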