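test_that("a single-AR map row reproduces the direct per-wavelength operations", {
  cfg <- run_config("gold", ar_grid = 1.5)
  m <- build_map("c_abs", cfg)
  geom <- nanorod_geometry(50, 1.5, mapping = cfg$mapping)
  exc <- excitation_response(geom, cfg$material, cfg$medium, cfg$placement,
                             cfg$lambda_grid)
  expect_identical(dim(m$values), c(1L, length(cfg$lambda_grid)))
  expect_equal(as.vector(m$values), exc$c_abs, tolerance = 1e-12)
  mxi <- build_map("xi", cfg)
  expect_equal(as.vector(mxi$values), exc$xi, tolerance = 1e-12)
})

test_that("index-matched particles give flat unit xi maps and zero absorption", {
  matched <- index_matched_material(1.33^2)
  cfg <- run_config(matched, ar_grid = c(1.1, 1.5), lambda_grid = seq(500, 600, by = 5))
  expect_equal(as.vector(build_map("xi", cfg)$values),
               rep(1, 2 * 21), tolerance = 1e-8)
  expect_true(all(abs(build_map("c_abs", cfg)$values) < 1e-6))
})

test_that("peak tracking refines interior maxima and flags edge cases", {
  lam <- seq(450, 700, by = 1)
  lorentz <- function(center, width) 1 / (1 + ((lam - center) / width)^2)
  mk <- function(rows) structure(list(quantity = "toy", lambda = lam,
                                      ar = seq_along(rows), values = do.call(rbind, rows)),
                                 class = "spectral_map")
  # symmetric curve centered at 600: recovered within 0.1 nm
  p <- track_peaks(mk(list(lorentz(600, 20))))
  expect_lt(abs(p$peak_lambda - 600), 0.1)
  expect_false(p$boundary)
  # off-grid center recovered too
  p2 <- track_peaks(mk(list(lorentz(587.4, 18))))
  expect_lt(abs(p2$peak_lambda - 587.4), 0.1)
  # plateau of equal maxima: leftmost reported, tie flagged
  plateau <- rep(0.5, length(lam)); plateau[lam >= 560 & lam <= 570] <- 1
  p3 <- track_peaks(mk(list(plateau)))
  expect_identical(p3$peak_lambda, 560)
  expect_true(p3$tie)
  # monotone row: boundary peak flagged, not refined
  p4 <- track_peaks(mk(list(seq_along(lam) / length(lam))))
  expect_true(p4$boundary)
  expect_identical(p4$peak_lambda, 700)
})

test_that("redshift of identical maps is zero and boundary peaks propagate as NA", {
  cfg <- run_config("gold", ar_grid = c(1.3, 1.5))
  m <- build_map("c_abs", cfg)
  expect_equal(redshift_xi_vs_cabs(m, m, 1.3), 0)
  lam <- seq(450, 700, by = 1)
  mono <- structure(list(quantity = "toy", lambda = lam, ar = 1.3,
                         values = matrix(lam, 1)), class = "spectral_map")
  expect_warning(rs <- redshift_xi_vs_cabs(mono, mono, 1.3), "boundary")
  expect_true(is.na(rs))
  expect_error(redshift_xi_vs_cabs(m, m, 2.0), "not in the map")
})

test_that("peak spacing ratio recovers a constructed compression factor", {
  lam <- seq(450, 700, by = 1)
  gauss_rows <- function(centers) do.call(rbind, lapply(centers, function(cc)
    exp(-0.5 * ((lam - cc) / 15)^2)))
  mk <- function(centers, q) structure(
    list(quantity = q, lambda = lam, ar = seq_along(centers),
         values = gauss_rows(centers)), class = "spectral_map")
  # C_abs peaks 25 nm apart, xi_eff peaks 5 nm apart: ratio 5 by construction
  ca <- mk(c(500, 525, 550, 575), "c_abs")
  xe <- mk(c(540, 545, 550, 555), "xi_eff")
  expect_equal(peak_spacing_ratio(ca, xe), 5, tolerance = 1e-6)
  expect_equal(peak_spacing_ratio(ca, ca), 1, tolerance = 1e-12)
  one_row <- mk(500, "c_abs")
  expect_error(peak_spacing_ratio(one_row, one_row), "at least 2")
})

test_that("gap sweep shows the enhancement/quenching competition on spheres", {
  # small gold sphere via the exact Mie backend: K(gap) must rise then fall
  cfg <- run_config("gold", ar_grid = 1, d = 20, gap = 5)
  gaps <- c(1, 2, 3, 5, 8, 12, 20, 35, 50)
  gs <- gap_sweep(cfg, gaps)
  kb <- gs$K_flu
  i_opt <- which.max(kb)
  expect_gt(i_opt, 1)
  expect_lt(i_opt, length(gaps))             # interior maximum
  expect_identical(attr(gs, "optimal_gap"), gaps[which.max(gs$K_flu_eff)])
  # far placement: enhancement factor returns to the free-space baseline Y0
  far <- gap_sweep(cfg, c(200))
  expect_equal(far$K_flu, cfg$spectra$Y0, tolerance = 0.02)
})

test_that("maps are deterministic and stable under wavelength-grid refinement", {
  cfg_a <- run_config("silver", ar_grid = c(1.3, 1.7))
  cfg_b <- run_config("silver", ar_grid = c(1.3, 1.7))
  expect_identical(build_map("K_flu_eff", cfg_a)$values,
                   build_map("K_flu_eff", cfg_b)$values)
  # halving the wavelength step moves refined peak positions by < 0.5 nm
  cfg_h <- run_config("silver", ar_grid = c(1.3, 1.7),
                      lambda_grid = seq(450, 700, by = 0.5))
  for (q in c("c_abs", "xi")) {
    p1 <- track_peaks(build_map(q, cfg_a))
    p2 <- track_peaks(build_map(q, cfg_h))
    expect_true(all(abs(p1$peak_lambda - p2$peak_lambda) < 0.5), label = q)
  }
})

test_that("the recommendation report is internally consistent", {
  cfg <- run_config("silver")
  rec <- recommend(cfg)
  expect_s3_class(rec, "optimization_report")
  expect_true(rec$optimal_ar >= min(cfg$ar_grid) && rec$optimal_ar <= max(cfg$ar_grid))
  expect_true(rec$lambda_excitation_opt >= min(cfg$lambda_grid) &&
                rec$lambda_excitation_opt <= max(cfg$lambda_grid))
  expect_equal(rec$lambda_emission_peak, cfg$spectra$lambda_em_peak)
  expect_gt(rec$K_peak, 0)
  expect_true(all(c("c_abs", "xi", "xi_eff") %in% names(rec$peaks)))
  # the reported K maximum matches the K_flu_eff map
  kmap <- build_map("K_flu_eff", cfg)
  expect_equal(rec$K_peak, max(kmap$values), tolerance = 1e-12)
})
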