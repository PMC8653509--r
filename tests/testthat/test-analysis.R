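test_that("group summaries average per pressure and flag singleton SDs", {
  s <- data.frame(applied_pressure_Pa = rep(c(1e5, 2e5), each = 3),
                  osm_flux_mOsm = c(300, 310, 320, 400, 410, 420),
                  hydration = c(5, 4.8, 5.2, 2, 2.2, 1.8))
  gr <- summarize_groups(s, reference_pressure = 1e5)
  expect_equal(gr$n, c(3, 3))
  expect_equal(gr$osm_flux_mOsm_mean, c(310, 410))
  expect_equal(gr$hydration_sd, c(sd(c(5, 4.8, 5.2)), sd(c(2, 2.2, 1.8))))
  # delta column relative to the reference group mean
  expect_equal(gr$delta_osm_mean, c(0, 100))
  # permutation invariance in sample order
  perm <- s[sample(nrow(s)), ]
  expect_equal(summarize_groups(perm, reference_pressure = 1e5), gr)
  # singleton group: SD 0 with flag
  g1 <- summarize_groups(data.frame(applied_pressure_Pa = 1e5,
                                    osm_flux_mOsm = 300))
  expect_equal(g1$osm_flux_mOsm_sd, 0)
  expect_true(g1$sd_flagged)
})

test_that("zero-noise cohort group means equal the generating relation exactly", {
  ct <- physical_constants()
  coh <- simulate_cohort(noise_free_config(seed = 6, samples_per_group = 3), ct)
  fit <- osmoflux(coh$flux, coh$calibration, constants = ct)
  gr <- fit$groups
  RT <- ct$gas_constant * ct$temperature
  expect_equal(gr$osm_flux_mOsm_mean, 279 + gr$applied_pressure_Pa / RT,
               tolerance = 1e-6)
})

test_that("ols_fit returns coefficients, R2 and slope p-value", {
  x <- 1:10
  f <- ols_fit(x, 2 * x, "linear")
  expect_equal(f$coefficients, c(0, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  f0 <- ols_fit(x, rep(3, 10), "linear")
  expect_equal(f0$coefficients[2], 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 0)
  # Table 1 group-mean flux osmolality vs pressure: slope 365, intercept 302
  t1 <- table1_means()
  ft <- ols_fit(t1$pressure_MPa, t1$osm_flux, "linear")
  expect_equal(signif(ft$coefficients[2], 3), 365)
  expect_equal(signif(ft$coefficients[1], 3), 302)
  # cross-check against the normal equations directly
  X <- cbind(1, t1$pressure_MPa)
  beta <- solve(t(X) %*% X, t(X) %*% t1$osm_flux)
  expect_equal(ft$coefficients, as.numeric(beta), tolerance = 1e-9)
  # quadratic form and degenerate designs
  fq <- ols_fit(1:5, (1:5)^2, "quadratic")
  expect_equal(fq$coefficients, c(0, 0, 1), tolerance = 1e-9)
  expect_error(ols_fit(1:2, 1:2, "linear"), "at least")
  expect_error(ols_fit(c(1, 1, 1), 1:3, "linear"), "rank")
})

test_that("diurnal extrapolation evaluates the fitted line at 0.2 and 0.6 MPa", {
  t1 <- table1_means()
  ft <- ols_fit(t1$pressure_MPa * 1e6, t1$osm_flux, "linear")
  d <- diurnal_extrapolation(ft)
  expect_equal(unname(d["osm_low"]), 374.76, tolerance = 1e-4)
  expect_equal(unname(d["osm_high"]), 520.73, tolerance = 1e-4)
  expect_equal(unname(d["magnitude"]), 145.97, tolerance = 1e-4)
  # endpoints within 0.3% of the published 376 / 522; magnitude rounds to 146
  expect_lt(abs(d["osm_low"] - 376) / 376, 0.005)
  expect_lt(abs(d["osm_high"] - 522) / 522, 0.005)
  expect_equal(round(unname(d["magnitude"])), 146)
  # slope 0 gives magnitude 0; magnitude is 0.4 MPa times the slope
  expect_equal(unname(diurnal_extrapolation(ols_fit(1:5 * 1e5, rep(7, 5)))["magnitude"]),
               0, tolerance = 1e-12)
  expect_equal(unname(d["magnitude"]), 0.4e6 * ft$coefficients[2],
               tolerance = 1e-9)
  # affine re-units of pressure leave consistently transformed endpoints alone
  ft_mpa <- ols_fit(t1$pressure_MPa, t1$osm_flux, "linear")
  d2 <- diurnal_extrapolation(ft_mpa, p_low = 0.2, p_high = 0.6)
  expect_equal(unname(d2), unname(d), tolerance = 1e-9)
  expect_error(diurnal_extrapolation(ols_fit(1:5, (1:5)^2, "quadratic")),
               "linear")
})

test_that("Lin's concordance follows its definition and known identities", {
  x <- c(1, 2, 3, 4)
  expect_equal(lins_concordance(x, x), 1)
  z <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(lins_concordance(z, -z), -1)
  # frozen value from direct evaluation of the population-moment definition
  expect_equal(lins_concordance(x, c(1.1, 2.1, 2.9, 4.2)), 0.993117,
               tolerance = 1e-6)
  # independent algebraic route: rho_c = r * C_b
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(8); b <- 0.5 * a + rnorm(8, 0.2, 0.3)
    r <- cor(a, b)
    sx <- sqrt(mean((a - mean(a))^2)); sy <- sqrt(mean((b - mean(b))^2))
    u <- (mean(a) - mean(b)) / sqrt(sx * sy)
    cb <- 2 / (sx / sy + sy / sx + u^2)
    expect_equal(lins_concordance(a, b), r * cb, tolerance = 1e-12)
    # rho_c never exceeds |r|
    expect_lte(abs(lins_concordance(a, b)), abs(r) + 1e-12)
  }
  # equal means and variances: rho_c equals Pearson r
  a <- rnorm(10); b <- rev(a)
  expect_equal(lins_concordance(a, b), cor(a, b), tolerance = 1e-12)
  expect_error(lins_concordance(c(1, 1), c(1, 1)), "undefined")
})

test_that("Spearman correlation handles monotone data and rejects constants", {
  expect_equal(spearman_rho(1:5, exp(1:5)), 1)
  expect_equal(spearman_rho(1:5, -(1:5)^3), -1)
  t1 <- table1_means()
  expect_equal(spearman_rho(t1$pressure_MPa, t1$hydration), -1)
  expect_equal(spearman_rho(t1$pressure_MPa, t1$na_molL), 1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length >= 3")
})

test_that("donnan_vs_flux_report joins, computes fractions and the load trend", {
  ct <- physical_constants()
  sw <- data.frame(sample_id = c("a", "b", "c", "d"),
                   applied_pressure_Pa = c(1e5, 1e5, 5e5, 5e5),
                   osm_flux_mOsm = c(320, 330, 500, 480))
  # identical osmolalities: all fractions 1
  dn_same <- data.frame(sample_id = sw$sample_id,
                        osm_icp_mOsm = sw$osm_flux_mOsm)
  rep1 <- donnan_vs_flux_report(dn_same, sw, ct)
  expect_equal(rep1$samples$donnan_fraction, rep(1, 4))
  # ionic share rising with load
  dn <- data.frame(sample_id = c("a", "b", "c", "d"),
                   osm_icp_mOsm = c(294, 297, 440, 430))
  rep2 <- donnan_vs_flux_report(dn, sw, ct)
  frac <- (dn$osm_icp_mOsm - 279) / (sw$osm_flux_mOsm - 279)
  expect_equal(sort(rep2$samples$donnan_fraction), sort(frac))
  expect_gt(rep2$trend, 0)
  expect_error(donnan_vs_flux_report(dn[1:3, ], sw, ct), "match")
})
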