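g <- probe_geometry()
ct <- physical_constants()

test_that("perfusion radius follows the volume balance", {
  expect_equal(perfusion_radius(0, 300, g), g$outer_membrane_radius)
  # q t = 3 pi L r2^2 gives r3 = 2 r2
  r2 <- g$outer_membrane_radius
  q <- 3 * pi * g$membrane_length * r2^2 / 300
  expect_equal(perfusion_radius(q, 300, g), 2 * r2, tolerance = 1e-12)
  # closed form vs numeric root of the volume balance
  q <- 1.890e-12
  r3 <- perfusion_radius(q, 300, g)
  expect_equal(r3, 2.247e-4, tolerance = 1e-3)
  root <- uniroot(function(r) pi * g$membrane_length * (r^2 - r2^2) - q * 300,
                  c(r2, 1e-2), tol = 1e-14)$root
  expect_equal(r3, root, tolerance = 1e-9)
  # strictly increasing in q
  qs <- seq(0, 5e-12, length.out = 20)
  expect_true(all(diff(perfusion_radius(qs, 300, g)) > 0))
  expect_error(perfusion_radius(-1e-12, 300, g), "sign")
})

test_that("radial stretch is the cube root of the mass ratio", {
  expect_equal(radial_stretch(1e-4, 1e-4), 1)
  expect_equal(radial_stretch(2e-4, 1e-4), 0.5^(1 / 3), tolerance = 1e-12)
  expect_equal(radial_stretch(2e-4, 1e-4), 0.7937, tolerance = 1e-4)
  expect_equal(radial_stretch(1e-4, 8e-4), 2)
  expect_error(radial_stretch(0, 1e-4), "positive")
})

test_that("strain-dependent tissue permeability matches its anchors", {
  expect_identical(tissue_permeability(1), 1.59e-15)
  expect_equal(tissue_permeability(0.6), 7.206e-16, tolerance = 1e-3)
  # vanishing base near pore closure
  expect_lt(tissue_permeability(0.2 + 1e-9), 1e-22)
  expect_error(tissue_permeability(0.2), "lambda")
  expect_error(tissue_permeability(0.1), "lambda")
  # strictly increasing on (0.2, 1]
  l <- seq(0.25, 1, by = 0.01)
  expect_true(all(diff(tissue_permeability(l)) > 0))
})

test_that("effective permeability is the log-weighted series combination", {
  r2 <- g$outer_membrane_radius
  # degenerate annulus: membrane only
  expect_equal(effective_total_permeability(1e-15, 5e-16, r2, g), 1e-15)
  # homogeneous medium
  expect_equal(effective_total_permeability(7e-16, 7e-16, 3e-4, g), 7e-16,
               tolerance = 1e-12)
  # brute-force series-resistance value from the module example
  gx <- probe_geometry(1.13e-4, 1.2e-4, 5e-3)
  expect_equal(effective_total_permeability(1e-15, 1.59e-15, 2.247e-4, gx),
               1.4666e-15, tolerance = 1e-4)
  # always between the two permeabilities
  set.seed(5)
  for (i in 1:30) {
    Km <- 10^runif(1, -18, -14); Kt <- 10^runif(1, -18, -14)
    r3 <- r2 * (1 + 10^runif(1, -3, 1))
    Ke <- effective_total_permeability(Km, Kt, r3, g)
    expect_gte(Ke, min(Km, Kt) * (1 - 1e-12))
    expect_lte(Ke, max(Km, Kt) * (1 + 1e-12))
  }
  expect_error(effective_total_permeability(1e-15, 1e-15, r2 * 0.99, g), "r3")
})

test_that("closed-form swelling pressure equals the integrated radial pressure drop", {
  set.seed(7)
  for (i in 1:40) {
    r1 <- runif(1, 0.5e-4, 2e-4)
    r2 <- r1 * (1 + runif(1, 0.01, 0.5))
    L <- runif(1, 2e-3, 10e-3)
    gx <- probe_geometry(r1, r2, L)
    Km <- 10^runif(1, -18, -15)
    Kt <- 10^runif(1, -17, -15)
    r3 <- r2 * (1 + 10^runif(1, -2, 1))
    q <- 10^runif(1, -14, -11)
    Ke <- effective_total_permeability(Km, Kt, r3, gx)
    dpi <- swelling_pressure_from_flux(q, Ke, r3, gx)
    expect_equal(dpi, integrated_pressure_drop(q, Km, Kt, r3, gx),
                 tolerance = 1e-9)
  }
})

test_that("swelling pressure is zero at zero flux and linear in q at fixed geometry", {
  expect_equal(swelling_pressure_from_flux(0, 1e-15, 3e-4, g), 0)
  d1 <- swelling_pressure_from_flux(1e-12, 1e-15, 3e-4, g)
  expect_equal(swelling_pressure_from_flux(2e-12, 1e-15, 3e-4, g), 2 * d1)
  # hydrostatic offset subtracts from the inferred osmotic difference
  expect_equal(swelling_pressure_from_flux(1e-12, 1e-15, 3e-4, g,
                                           hydrostatic_offset = 100),
               d1 - 100)
})

test_that("osmolality-pressure conversion uses the 279 mOsm/kg bath baseline", {
  expect_equal(bath_osmolality(ct), 279)
  expect_equal(osmolality_from_pressure(0, ct), 279)
  # 552.9 kPa above bath, the highest-pressure group scale
  expect_equal(osmolality_from_pressure(552.9e3, ct), 502, tolerance = 1e-3)
  # inverse round-trip
  for (o in c(279, 293, 380, 502))
    expect_equal(osmolality_from_pressure(pressure_from_osmolality(o, ct), ct),
                 o, tolerance = 1e-12)
  expect_error(osmolality_from_pressure(-1e6, ct), "negative")
})

test_that("infer_sample chains the inference and reports perfused volume", {
  rec <- data.frame(sample_id = "s1", applied_pressure_Pa = 0.21e6,
                    m0_kg = 2e-4, mf_kg = 1.5e-4, post_flux_wet_kg = 1.5e-4,
                    dry_kg = 0.4e-4, q1_m3s = 0, q2_m3s = 0, q3_m3s = 0,
                    t_s = 300)
  out <- infer_sample(rec, K_mem = 1e-17, geometry = g, constants = ct)
  expect_equal(out$delta_pi_Pa, 0)
  expect_equal(out$osm_flux_mOsm, 279)
  expect_equal(out$r3, g$outer_membrane_radius)

  # triplicates are averaged before inference
  K <- 1e-17
  lambda <- radial_stretch(rec$m0_kg, rec$mf_kg)
  q_star <- forward_flux(0.3e6, K, lambda, 300, g)
  rec2 <- rec
  rec2[c("q1_m3s", "q2_m3s", "q3_m3s")] <- q_star * c(0.9, 1.0, 1.1)
  out2 <- infer_sample(rec2, K, g, ct)
  expect_equal(out2$q_mean, q_star, tolerance = 1e-12)
  expect_equal(out2$delta_pi_Pa, 0.3e6, tolerance = 1e-9)
  # missing triplicates tolerated
  rec3 <- rec2
  rec3$q2_m3s <- NA; rec3$q3_m3s <- NA
  expect_equal(infer_sample(rec3, K, g, ct)$q_mean, q_star * 0.9,
               tolerance = 1e-12)
})
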