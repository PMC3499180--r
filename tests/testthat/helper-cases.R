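# Shared fixtures built in code.

tabulated_loads <- function() gp_load_cases()$delta_sigma_n

# Kinetic closure for one load case: h_p from zone filling, n_p from the
# one-cell-per-interval equilibrium, t_E from column traversal.
kinetic_closure <- function(load) {
  lc <- get_load_case(load)
  list(lc = lc,
       l_p = lc$thickness[["proliferative"]],
       l_h = lc$thickness[["hypertrophic"]],
       h_p = lc$thickness[["proliferative"]] / lc$cells[["proliferative"]],
       n_p = 1 / lc$delta_t,
       t_E = lc$cells[["hypertrophic"]] * lc$delta_t)
}

# Uniform materials table (homogenises the five-region mesh for patch tests).
uniform_materials <- function(E = 2000, nu = 0.3) {
  data.frame(tissue = gp_tissues()$tissue,
             youngs_modulus_mpa = E, poisson_ratio = nu)
}

baseline_mesh <- function(load = 0, ...) {
  generate_mesh(build_domain(get_load_case(load)), ...)
}
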