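# shared fixtures built in code

noise_free_config <- function(seed = 1L, ...) {
  sim_config(flux_rel_sd = 0, sodium_rel_sd = 0, mass_rel_sd = 0,
             membrane_K_rel_sd = 0, seed = seed, ...)
}

# numeric oracle for the radial Darcy pressure drop: integrate
# dP/dr = q / (2 pi r L K(r)) over piecewise-constant permeability
# (membrane annulus then tissue annulus), independent of the closed form
integrated_pressure_drop <- function(q, K_mem, K_tissue, r3, geometry) {
  L <- geometry$membrane_length
  f <- function(r, K) q / (2 * pi * r * L * K)
  stats::integrate(f, geometry$inner_membrane_radius,
                   geometry$outer_membrane_radius, K = K_mem,
                   rel.tol = 1e-12)$value +
    stats::integrate(f, geometry$outer_membrane_radius, r3, K = K_tissue,
                     rel.tol = 1e-12)$value
}

# Table 1 printed group means (the published cohort-level inputs)
table1_means <- function() {
  data.frame(
    pressure_MPa = c(0.03, 0.10, 0.21, 0.37, 0.57),
    hydration = c(4.96, 4.16, 2.78, 2.30, 1.64),
    na_molL = c(0.18, 0.22, 0.27, 0.34, 0.41),
    total_ions_molL = c(0.31, 0.32, 0.36, 0.41, 0.46),
    fcd = c(0.05, 0.12, 0.18, 0.28, 0.35),
    osm_icp = c(284, 302, 331, 381, 432),
    osm_flux = c(293, 357, 379, 445, 502))
}
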