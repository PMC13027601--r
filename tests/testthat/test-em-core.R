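med <- medium(1.33)
gold <- mef_material("gold")

test_that("an index-matched particle is electromagnetically invisible", {
  matched <- index_matched_material(med$eps)
  pl <- emitter_placement(5)
  lam <- c(500, 584, 650)
  for (backend in c("mie_sphere", "spheroid_mlwa")) {
    geom <- nanorod_geometry(40, 1)
    exc <- excitation_response(geom, matched, med, pl, lam, backend = backend)
    expect_equal(exc$xi, rep(1, 3), tolerance = 1e-8)
    expect_true(all(abs(exc$c_abs) < 1e-6))
    expect_true(all(abs(exc$c_sca) < 1e-6))
    em <- emission_response(geom, matched, med, pl, lam, backend = backend)
    expect_equal(em$gamma_rad, rep(1, 3), tolerance = 1e-8)
    expect_equal(em$gamma_nr, rep(0, 3), tolerance = 1e-8)
  }
})

test_that("Mie cross-sections reach the Rayleigh closed form for tiny spheres", {
  geom <- nanorod_geometry(1, 1)   # x ~ 0.006 at 650 nm
  pl <- emitter_placement(5)
  for (lam in c(532, 650)) {
    exc <- excitation_response(geom, gold, med, pl, lam)
    eps <- permittivity(gold, lam)
    ray <- rayleigh_xs_oracle(eps, med$eps, 0.5, lam)
    expect_equal(exc$c_sca, ray[["c_sca"]], tolerance = 0.01)
    expect_equal(exc$c_abs, ray[["c_abs"]], tolerance = 0.01)
    expect_equal(exc$c_ext, ray[["c_ext"]], tolerance = 0.01)
  }
})

test_that("Mie dipole rates match the quasistatic image-multipole oracle", {
  geom <- nanorod_geometry(10, 1)
  pl <- emitter_placement(5)
  for (lam in c(532, 650)) {
    em <- emission_response(geom, gold, med, pl, lam)
    k <- 2 * pi * 1.33 / lam
    qs <- qs_rates_radial_oracle(permittivity(gold, lam) / med$eps,
                                 a = 5, r = 10, k = k)
    expect_equal(em$gamma_rad, qs[["gamma_rad"]], tolerance = 0.05)
    expect_equal(em$gamma_nr, qs[["gamma_nr"]], tolerance = 0.05)
  }
})

test_that("a lossless sphere absorbs nothing from a nearby dipole", {
  glass <- lossless_material(2.25)
  geom <- nanorod_geometry(40, 1)
  for (ori in c("perpendicular", "parallel")) {
    em <- emission_response(geom, glass, med, emitter_placement(5, ori), 584)
    expect_lt(abs(em$gamma_nr), 1e-8)
    expect_gt(em$gamma_rad, 0)
  }
})

test_that("rates reach the isolated-molecule limit far from the particle", {
  geom <- nanorod_geometry(20, 1)
  for (ori in c("perpendicular", "parallel")) {
    em <- emission_response(geom, gold, med, emitter_placement(200, ori), 584)
    expect_equal(em$gamma_rad, 1, tolerance = 0.01)
    expect_lt(abs(em$gamma_nr), 0.01)
  }
})

test_that("Mie and MLWA backends agree for small spheres (shared validity regime)", {
  geom <- nanorod_geometry(10, 1)
  pl <- emitter_placement(5)
  lam <- c(480, 520, 560, 600, 650)
  e_mie <- excitation_response(geom, gold, med, pl, lam, backend = "mie_sphere")
  e_sph <- excitation_response(geom, gold, med, pl, lam, backend = "spheroid_mlwa")
  expect_equal(e_mie$c_ext, e_sph$c_ext, tolerance = 0.02)
  expect_equal(e_mie$c_sca, e_sph$c_sca, tolerance = 0.02)
  expect_equal(e_mie$xi, e_sph$xi, tolerance = 0.02)
})

test_that("non-radiative quenching grows monotonically as the gap closes", {
  geom <- nanorod_geometry(20, 1)
  gaps <- c(8, 4, 2, 1)
  gnr <- vapply(gaps, function(g)
    emission_response(geom, gold, med, emitter_placement(g), 650)$gamma_nr,
    numeric(1))
  expect_true(all(diff(gnr) > 0))
})

test_that("the tabulated backend serves exact rows and interpolates between them", {
  dir <- withr::local_tempdir()
  generate_fixtures(dir)
  tb <- tabulated_backend(file.path(dir, "tabulated_backend_gold_ar1.5.csv"))
  geom <- nanorod_geometry(50, 1.5)
  pl <- emitter_placement(6)
  df <- utils::read.csv(file.path(dir, "tabulated_backend_gold_ar1.5.csv"))
  # exact passthrough at a tabulated wavelength
  exc <- excitation_response(geom, gold, med, pl, df$wavelength_nm[3], backend = tb)
  expect_equal(exc$xi, df$xi[3], tolerance = 1e-9)
  expect_equal(exc$c_abs, df$c_abs_nm2[3], tolerance = 1e-9)
  # linear interpolation between rows
  mid <- (df$wavelength_nm[3] + df$wavelength_nm[4]) / 2
  exc_mid <- excitation_response(geom, gold, med, pl, mid, backend = tb)
  expect_equal(exc_mid$xi, (df$xi[3] + df$xi[4]) / 2, tolerance = 1e-9)
  em_mid <- emission_response(geom, gold, med, pl, mid, backend = tb)
  expect_equal(em_mid$gamma_rad, (df$gamma_rad_norm[3] + df$gamma_rad_norm[4]) / 2,
               tolerance = 1e-9)
  expect_error(excitation_response(geom, gold, med, pl, 100, backend = tb),
               "span")
})

test_that("backend registry enforces names and capabilities", {
  expect_true(all(c("mie_sphere", "spheroid_mlwa") %in% list_backends()))
  dummy <- list(ar_range = c(1, 1), orientations = "perpendicular",
                excitation = function(...) NULL, emission = function(...) NULL)
  register_backend("dummy_test_backend", dummy, overwrite = TRUE)
  expect_error(register_backend("dummy_test_backend", dummy), "already")
  expect_error(register_backend("incomplete", list(a = 1)), "must provide")
  # capability mismatch: sphere-only backend asked for a rod
  geom <- nanorod_geometry(50, 1.5)
  expect_error(
    excitation_response(geom, gold, med, emitter_placement(6), 550,
                        backend = "dummy_test_backend"),
    "supports AR")
  expect_error(
    emission_response(nanorod_geometry(50, 1), gold, med,
                      emitter_placement(6, "parallel"), 550,
                      backend = "dummy_test_backend"),
    "orientation")
  expect_error(excitation_response(geom, gold, med, emitter_placement(6),
                                   550, backend = "no_such"),
               "unknown backend")
})

test_that("geometry and placement constructors validate their domain", {
  g <- nanorod_geometry(50, 1)
  expect_equal(g$L, 50)                      # AR = 1 is a sphere
  expect_equal(g$semi_major, 25)
  g2 <- nanorod_geometry(50, 1.8, mapping = "volume")
  expect_equal(g2$ar_eff, 1.5 * 1.8 - 0.5)
  expect_equal(g2$L - g2$d, 40)              # cylindrical mid-section length
  g3 <- nanorod_geometry(50, 1.8, mapping = "length")
  expect_equal(g3$semi_major, 45)
  expect_error(nanorod_geometry(50, 0.8), "aspect ratio")
  expect_error(nanorod_geometry(-1, 1.5), "diameter")
  expect_error(emitter_placement(0), "positive")
  expect_error(emitter_placement(-2), "positive")
  expect_warning(emitter_placement(0.5), "sub-nm")
})

test_that("near-field and emission enhancements peak together (reciprocity)", {
  cfg <- run_config("gold", ar_grid = 1.5)
  p_xi <- track_peaks(build_map("xi", cfg))
  p_gr <- track_peaks(build_map("gamma_rad", cfg))
  expect_lt(abs(p_xi$peak_lambda - p_gr$peak_lambda), 5)
})
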