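ct <- physical_constants()

test_that("hydration is (wet - dry)/dry", {
  expect_equal(hydration(1e-4, 1e-4), 0)
  expect_equal(hydration(2e-4, 1e-4), 1)
  expect_equal(hydration(5.96e-5, 1e-5), 4.96)
  expect_error(hydration(0.5e-4, 1e-4), "below")
  expect_error(hydration(1e-4, 0), "positive")
})

test_that("sodium concentration normalizes moles to TTW volume", {
  # 1.8e-4 mol in 1 mL TTW (1 g water) is 0.18 mol/L
  expect_equal(sodium_concentration(1.8e-4, 1.1e-3, 0.1e-3), 0.18)
  expect_equal(sodium_concentration(0, 1.1e-3, 0.1e-3), 0)
  expect_equal(sodium_concentration(3.6e-4, 1.1e-3, 0.1e-3), 0.36)
  expect_error(sodium_concentration(1e-4, 1e-3, 1e-3), "exceed")
})

test_that("Donnan relations reproduce the Table 1 chain from mean sodium", {
  # partition coefficient
  expect_equal(partition_coefficient(0.15), 1)
  expect_equal(partition_coefficient(0.18), 1.2)
  expect_equal(partition_coefficient(0.41), 2.7333, tolerance = 1e-4)
  expect_warning(partition_coefficient(0.10), "negative fixed charge")

  # fixed charge density: c_na - c_ext^2/c_na, both algebraic forms agree
  expect_equal(fixed_charge_density(0.15), 0)
  expect_equal(fixed_charge_density(0.41), 0.41 - 0.15^2 / 0.41)
  expect_equal(fixed_charge_density(0.41), 0.3551, tolerance = 1e-4)
  expect_equal(fixed_charge_density(0.18), 0.0550, tolerance = 1e-3)

  # chloride
  expect_equal(intratissue_chloride(0.15), 0.15)
  expect_equal(intratissue_chloride(0.18), 0.1250)
  expect_equal(intratissue_chloride(0.41), 0.05488, tolerance = 1e-4)

  # total ions, rounded half-up to 2 dp as printed
  r2dp <- function(x) osmoflux:::round_half_up(x, 2)
  expect_equal(r2dp(total_ion_concentration(0.18)), 0.31)
  expect_equal(r2dp(total_ion_concentration(0.34)), 0.41)
  expect_equal(r2dp(total_ion_concentration(0.41)), 0.46)
  expect_equal(total_ion_concentration(0.15), 0.30)

  # osmolality from ions, integer rounding as printed
  expect_equal(round(osmolality_from_ions(total_ion_concentration(0.18))), 284)
  expect_equal(round(osmolality_from_ions(total_ion_concentration(0.41))), 432)
  expect_equal(osmolality_from_ions(0), 0)
})

test_that("Donnan ion product and electroneutrality hold for any sodium input", {
  set.seed(13)
  cna <- exp(runif(50, log(0.15), log(1.2)))
  ccl <- intratissue_chloride(cna)
  cf <- fixed_charge_density(cna)
  expect_equal(cna * ccl, rep(0.15^2, 50), tolerance = 1e-12)
  expect_equal(cf + ccl, cna, tolerance = 1e-15)
})

test_that("ionic swelling pressure matches its closed form, small-cf limit and convexity", {
  expect_equal(ionic_swelling_pressure(0, ct), 0)
  # direct arithmetic at the 0.57 MPa group's FCD
  RT <- 8.314 * 298.15
  cf <- 0.3551
  expect_equal(ionic_swelling_pressure(cf, ct),
               0.93 * RT * (sqrt((cf * 1000)^2 + 4 * 150^2) - 300))
  expect_equal(ionic_swelling_pressure(cf, ct), 3.799e5, tolerance = 1e-3)
  # Taylor expansion oracle: phi RT cf^2/(4 cext) within 1% for cf <= 0.02
  for (cf in c(0.005, 0.01, 0.02)) {
    approx <- 0.93 * RT * (cf * 1000)^2 / (4 * 150)
    expect_equal(ionic_swelling_pressure(cf, ct), approx, tolerance = 0.01)
  }
  # strictly increasing and convex in cf
  cfs <- seq(0, 1, by = 0.02)
  p <- sapply(cfs, ionic_swelling_pressure, constants = ct)
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(diff(p)) > 0))
  # large-cf limit: sqrt(cf^2 + 4 cext^2) - cf tends to 0
  tail_gap <- sqrt((cfs * 1000)^2 + 4 * 150^2) - cfs * 1000
  expect_true(all(diff(tail_gap) < 0))
  expect_error(ionic_swelling_pressure(-0.1, ct), "negative")
})

test_that("osmolality from ions and from pressure agree through shared constants", {
  # same underlying pi/RT: ionic swelling pressure converted to osmolality
  # must equal phi * total_ions * 1000
  for (cna in c(0.18, 0.27, 0.41)) {
    cf <- fixed_charge_density(cna)
    osm_a <- osmolality_from_ions(total_ion_concentration(cna),
                                  ct$osmotic_coefficient)
    osm_b <- osmolality_from_pressure(ionic_swelling_pressure(cf, ct), ct)
    expect_equal(osm_a, osm_b, tolerance = 1e-12)
  }
})

test_that("donnan_fraction measures the ionic share above bath", {
  expect_equal(donnan_fraction(300, 300, ct), 1)
  expect_equal(donnan_fraction(279, 300, ct), 0)
  # the printed low-load group: 35.7% of flux swelling explained by Donnan
  expect_equal(donnan_fraction(284, 293, ct), 5 / 14, tolerance = 1e-12)
  expect_error(donnan_fraction(284, 279, ct), "bath")
})

test_that("donnan_state assembles the per-sample ionic state with flags", {
  rec <- list(sample_id = "s1", na_mol = 1.8e-4, wet_kg = 1.1e-3, dry_kg = 1e-4)
  st <- donnan_state(rec, ct)
  expect_equal(st$c_na_int, 0.18)
  expect_equal(st$fcd, fixed_charge_density(0.18))
  expect_equal(st$c_na_int * st$c_cl_int, 0.15^2, tolerance = 1e-12)
  expect_equal(st$hydration, 10)
  expect_false(st$donnan_flag)
  # sodium below bath is flagged but carried through
  rec$na_mol <- 1.0e-4
  st2 <- suppressWarnings(donnan_state(rec, ct))
  expect_true(st2$donnan_flag)
  expect_true(st2$fcd < 0)
  # EFW renormalization raises concentrations
  st3 <- donnan_state(list(sample_id = "s1", na_mol = 1.8e-4, wet_kg = 1.1e-3,
                           dry_kg = 1e-4), ct, water_fraction = 0.9)
  expect_equal(st3$c_na_int, 0.18 / 0.9)
  expect_error(donnan_state(rec, ct, water_fraction = 0), "water_fraction")
})

test_that("bath drift beyond 1% draws a warning", {
  expect_silent(pct <- bath_drift(0.15, 0.15 * 1.0039))
  expect_equal(pct, 0.39, tolerance = 1e-10)
  expect_warning(bath_drift(0.15, 0.157), "more than 1")
})
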