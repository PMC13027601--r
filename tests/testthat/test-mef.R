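test_that("spectral weighting of the field enhancement is a plain product", {
  expect_identical(xi_eff(100, 1), 100)     # at the excitation peak
  expect_identical(xi_eff(100, 0), 0)       # outside the excitation band
  expect_identical(xi_eff(50, 0.4), 20)
  expect_equal(xi_eff(c(1, 2), c(0.5, 0.25)), c(0.5, 0.5))
  expect_error(xi_eff(-1, 0.5), "non-negative")
  expect_error(xi_eff(1, 1.5), "normalized")
})

test_that("effective rates scale both channels by the emission spectrum", {
  rates <- data.frame(gamma_rad = 4, gamma_nr = 2)
  r <- effective_rates(rates, 0.5)
  expect_identical(r$gamma_rad_eff, 2)
  expect_identical(r$gamma_nr_eff, 1)
  r1 <- effective_rates(rates, 1)
  expect_identical(r1$gamma_rad_eff, 4)     # emission-peak identity
  r0 <- effective_rates(rates, 0)
  expect_identical(r0$gamma_rad_eff, 0)
  expect_error(effective_rates(rates, 1.5), "\\[0, 1\\]")
})

test_that("the modified quantum yield follows its defining formula", {
  expect_equal(quantum_yield_eff(1, 0, 0.5), 0.5)    # isolated molecule -> Y0
  expect_equal(quantum_yield_eff(1, 0, 1), 1)        # unit-yield limit
  expect_equal(quantum_yield_eff(10, 5, 0.5), 10 / 16)
  # 0/0 convention: no rates, Y0 = 1 -> no emission in band
  expect_identical(quantum_yield_eff(0, 0, 1), 0)
  expect_identical(quantum_yield_eff(0, 5, 0.5), 0)
  expect_error(quantum_yield_eff(1, 0, 0), "Y0")
  expect_error(quantum_yield_eff(-1, 0, 0.5), ">= 0")
  # vectorized and bounded
  y <- quantum_yield_eff(runif(50, 0, 20), runif(50, 0, 50), 0.48)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("K_flu reduces to the free-space baseline without a particle", {
  med <- medium(1.33)
  matched <- index_matched_material(med$eps)
  geom <- nanorod_geometry(40, 1)
  pl <- emitter_placement(5)
  lam <- seq(500, 650, by = 1)
  sp <- tagrfp_spectra(grid = lam)
  exc <- excitation_response(geom, matched, med, pl, lam, backend = "spheroid_mlwa")
  em <- emission_response(geom, matched, med, pl, lam, backend = "spheroid_mlwa")
  tm <- tm_quantities(exc, em, sp)
  expect_equal(tm$K_flu, sp$Y0, tolerance = 1e-8)    # xi = 1, Y = Y0
  expect_equal(tm$fold_enhancement, 1, tolerance = 1e-8)
  expect_identical(k_flu_eff(5, 0), 0)               # zero yield, zero K
})

test_that("TM and RM agree for delta-like spectra and diverge for wide bands", {
  med <- medium(1.33)
  gold <- mef_material("gold")
  geom <- nanorod_geometry(50, 1.5)
  pl <- emitter_placement(6)
  lam <- seq(450, 700, by = 1)
  exc <- excitation_response(geom, gold, med, pl, lam)
  em <- emission_response(geom, gold, med, pl, lam)
  # delta-like: only the 555/584 nm nodes carry weight
  reldiff <- vapply(c(5, 1, 0.5, 0.15), function(w) {
    sp <- synth_spectra(555, 584, w, w, Y0 = 0.48, grid = lam)
    r <- rm_quantities(exc, em, sp)
    t <- tm_quantities(exc, em, sp)
    abs(r$K_flu_eff - t$K_flu) / t$K_flu
  }, numeric(1))
  expect_true(all(diff(reldiff) < 0))        # convergence as widths shrink
  expect_lt(reldiff[4], 1e-6)
})

test_that("the effective yield never exceeds the monochromatic yield (Y0 < 1)", {
  cfg <- run_config("gold")
  ymap <- build_map("Y", cfg)
  yeffmap <- build_map("Y_eff", cfg)
  expect_true(all(yeffmap$values <= ymap$values + 1e-12))
  # and every RM/TM quantity is non-negative over the whole (lambda x AR) grid
  for (q in c("xi", "xi_eff", "c_abs", "c_sca", "c_ext", "gamma_rad",
              "gamma_nr", "gamma_rad_eff", "gamma_nr_eff", "Y", "Y_eff",
              "K_flu", "K_flu_eff")) {
    expect_true(all(build_map(q, cfg)$values >= 0), label = q)
  }
})

test_that("the integral criterion is linear and matches a fine-grid oracle", {
  med <- medium(1.33)
  gold <- mef_material("gold")
  pl <- emitter_placement(6)
  lam <- seq(450, 700, by = 1)
  sp <- tagrfp_spectra(grid = lam)
  crit <- function(ar) {
    geom <- nanorod_geometry(50, ar)
    exc <- excitation_response(geom, gold, med, pl, lam)
    em <- emission_response(geom, gold, med, pl, lam)
    r <- rm_quantities(exc, em, sp)
    list(value = integral_criterion(r, sp), rm = r, em = em)
  }
  c13 <- crit(1.3); c19 <- crit(1.9)
  # ranking agrees with an independent 0.1 nm midpoint-rule re-integration
  o13 <- total_power_oracle(lam, c13$em$gamma_rad, sp, c13$rm$xi_eff)
  o19 <- total_power_oracle(lam, c19$em$gamma_rad, sp, c19$rm$xi_eff)
  expect_identical(c13$value > c19$value, o13 > o19)
  expect_equal(c13$value, o13, tolerance = 0.01)
  # scaling all effective radiative rates by c scales the criterion by c
  r2 <- c13$rm
  r2$gamma_rad_eff <- 3 * r2$gamma_rad_eff
  expect_equal(integral_criterion(r2, sp), 3 * c13$value, tolerance = 1e-9)
})

test_that("a uniform effective rate integrates to support width times max xi_eff", {
  lam <- seq(550, 650, by = 1)
  sp <- fluorophore_spectra(lam, ex = exp(-0.5 * ((lam - 550) / 8)^2),
                            em = rep(1, length(lam)), Y0 = 0.5)
  fake <- structure(list(model = "RM", wavelength = lam,
                         gamma_rad_eff = rep(1, length(lam)),
                         xi_eff = rep(2.5, length(lam))),
                    class = "mef_result")
  expect_equal(integral_criterion(fake, sp, photon_weight = FALSE), 100 * 2.5)
  # empty support -> 0 with a warning
  sp_out <- synth_spectra(450, 470, 4, 4, Y0 = 0.5, grid = seq(440, 500, by = 1))
  expect_warning(v <- integral_criterion(fake, sp_out), "support")
  expect_identical(v, 0)
})
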