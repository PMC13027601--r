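# Run configuration, fixture generation, and bit-stable CSV/JSON readers
# and writers.

#' Validated run configuration
#'
#' Bundles every input of a sweep: material, medium, geometry grid,
#' placement, fluorophore, wavelength grid, model, backend, and seed. The
#' configuration is validated on construction and hashed; the hash is
#' embedded in every output file so runs are self-documenting. Defaults
#' follow the study conditions of the gold/silver nanorod-TagRFP
#' complexes: d = 50 nm rods in water, AR from 1.1 to 2.1 in steps of 0.2,
#' a 6 nm gap for gold and 3 nm for silver, wavelengths 450-700 nm in 1 nm
#' steps.
#'
#' @param metal `"gold"`, `"silver"`, or a [material_model()].
#' @param d Nanorod diameter in nm.
#' @param ar_grid Aspect-ratio grid (all >= 1).
#' @param gap Molecule-surface gap in nm; default 6 (gold) or 3 (silver).
#' @param orientation Dipole orientation, see [emitter_placement()].
#' @param mapping Rod-to-spheroid mapping, see [nanorod_geometry()].
#' @param medium_index Host refractive index (default water, 1.33).
#' @param lambda_grid Wavelength grid in nm.
#' @param spectra A [fluorophore_spectra()]; default TagRFP-like synthetic
#'   spectra with `Y0`.
#' @param Y0 Intrinsic quantum yield used when `spectra` is `NULL`
#'   (default 0.48, the published TagRFP value; the choice is logged in
#'   the config echo of every output).
#' @param model `"rm"` (spectrally refined) or `"tm"` (monochromatic).
#' @param backend Backend name or object; `NULL` for default dispatch.
#' @param lambda_exc Optional fixed excitation wavelength for the RM model.
#' @param seed Integer seed recorded with the run (randomized studies only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(metal = "gold", d = 50,
                       ar_grid = seq(1.1, 2.1, by = 0.2), gap = NULL,
                       orientation = "perpendicular",
                       mapping = "volume", medium_index = 1.33,
                       lambda_grid = seq(450, 700, by = 1),
                       spectra = NULL, Y0 = 0.48, model = c("rm", "tm"),
                       backend = NULL, lambda_exc = NULL, seed = 1L) {
  model <- match.arg(model)
  if (inherits(metal, "mef_material")) {
    material <- metal
    metal_name <- material$name
  } else {
    metal_name <- match.arg(metal, c("gold", "silver"))
    material <- mef_material(metal_name)
  }
  if (is.null(gap)) gap <- if (metal_name == "silver") 3 else 6
  if (is.null(spectra)) spectra <- tagrfp_spectra(Y0 = Y0)
  stopifnot(inherits(spectra, "fluorophore_spectra"))
  if (!is.numeric(ar_grid) || any(ar_grid < 1)) stop("ar_grid entries must be >= 1")
  if (any(diff(ar_grid) <= 0)) stop("ar_grid must be strictly increasing")
  if (any(diff(lambda_grid) <= 0)) stop("lambda_grid must be strictly increasing")
  cfg <- list(metal = metal_name, material = material,
              medium = medium(medium_index), d = d, ar_grid = ar_grid,
              placement = emitter_placement(gap, orientation),
              mapping = mapping, lambda_grid = lambda_grid,
              spectra = spectra, model = model, backend = backend,
              lambda_exc = lambda_exc, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s rod d = %g nm, AR %s, gap %g nm (%s), %s model\n",
              x$metal, x$d,
              paste0("[", min(x$ar_grid), ", ", max(x$ar_grid), "]"),
              x$placement$gap, x$placement$orientation, toupper(x$model)))
  cat(sprintf("  medium n = %g; lambda %g-%g nm; Y0 = %g; hash %s\n",
              x$medium$refractive_index, min(x$lambda_grid),
              max(x$lambda_grid), x$spectra$Y0, x$hash))
  invisible(x)
}

# Content hash of a configuration (timestamp-free, whitespace-stable).
config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# Summarize a config as a plain list for JSON echoes.
config_echo <- function(config) {
  list(metal = config$metal, material = config$material$name,
       d_nm = config$d, ar_grid = config$ar_grid,
       gap_nm = config$placement$gap,
       orientation = config$placement$orientation,
       mapping = config$mapping,
       medium_index = config$medium$refractive_index,
       lambda_nm = range(config$lambda_grid),
       Y0 = config$spectra$Y0,
       lambda_ex_peak = config$spectra$lambda_ex_peak,
       lambda_em_peak = config$spectra$lambda_em_peak,
       model = config$model,
       backend = if (is.null(config$backend)) "auto" else
         if (is.character(config$backend)) config$backend else config$backend$name,
       seed = config$seed, config_hash = config$hash)
}

#' Write a spectral map as long-format CSV
#'
#' Columns `model, quantity, lambda_nm, ar, gap_nm, value`, preceded by a
#' comment header embedding the configuration hash. Values round-trip at 12
#' significant digits.
#'
#' @param map A [build_map()] result.
#' @param path Output CSV path.
#' @param config Optional [run_config()] for the metadata header.
#' @param model Model label stored in the `model` column.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, config = NULL, model = "rm") {
  stopifnot(inherits(map, "spectral_map"))
  df <- data.frame(
    model = model, quantity = map$quantity,
    lambda_nm = rep(map$lambda, each = length(map$ar)),
    ar = rep(map$ar, times = length(map$lambda)),
    gap_nm = if (is.null(config)) NA_real_ else config$placement$gap,
    value = as.vector(map$values))
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (!is.null(config)) config$hash else
    if (!is.null(map$config_hash)) map$config_hash else "unknown"
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format spectral map CSV
#'
#' Validates the schema and rejects non-finite values, reporting the
#' offending row number.
#'
#' @param path CSV written by [write_map()].
#' @return A `spectral_map`.
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("model", "quantity", "lambda_nm", "ar", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("map CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$value))
  if (length(bad)) stop("non-finite map value at row ", bad[1])
  lam <- sort(unique(df$lambda_nm))
  ars <- sort(unique(df$ar))
  vals <- matrix(NA_real_, length(ars), length(lam))
  vals[cbind(match(df$ar, ars), match(df$lambda_nm, lam))] <- df$value
  if (any(!is.finite(vals))) stop("map CSV is not a complete (ar x lambda) grid")
  structure(list(quantity = df$quantity[1], lambda = lam, ar = ars,
                 values = vals),
            class = "spectral_map")
}

#' Write an optimization report as JSON
#'
#' @param report An [recommend()] result.
#' @param path Output JSON path.
#' @param config Optional [run_config()] echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "optimization_report"))
  out <- unclass(report)
  out$peaks <- lapply(out$peaks, function(df) as.list(df))
  if (!is.null(config)) out$config <- config_echo(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an optimization report JSON
#'
#' @param path JSON written by [write_report()].
#' @return Named list; errors name any missing required key.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("optimal_ar", "K_peak", "lambda_excitation_opt",
           "lambda_emission_peak")
  miss <- setdiff(req, names(rep))
  if (length(miss)) stop("report missing required keys: ",
                         paste(miss, collapse = ", "))
  rep
}

#' Generate test fixtures
#'
#' Writes deterministic, plain-text fixtures into a directory: TagRFP-like
#' synthetic spectra, a toy three-node material table, and a tabulated
#' backend CSV built from the MLWA spheroid response of the default gold
#' configuration (row-wise satisfying `c_ext = c_abs + c_sca`). Returns a
#' manifest of files and MD5 checksums; two runs produce identical files.
#'
#' @param out_dir Writable output directory (created if needed).
#' @return Data frame with columns `file`, `md5`.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # 1. TagRFP-like synthetic spectra
  sp <- tagrfp_spectra(grid = seq(450, 700, by = 1))
  f1 <- file.path(out_dir, "tagrfp_synthetic_spectra.csv")
  write_spectra_csv(sp, f1)
  # 2. toy material table
  f2 <- file.path(out_dir, "toy_material.csv")
  writeLines(c("wavelength_nm,eps_re,eps_im",
               "400,-2.5,1.2", "550,-6.0,0.8", "700,-12.0,1.1"), f2)
  # 3. tabulated backend export from the spheroid surrogate
  geom <- nanorod_geometry(50, 1.5)
  mat <- mef_material("gold")
  med <- medium(1.33)
  pl <- emitter_placement(6)
  lam <- seq(450, 700, by = 5)
  exc <- excitation_response(geom, mat, med, pl, lam, backend = "spheroid_mlwa")
  em <- emission_response(geom, mat, med, pl, lam, backend = "spheroid_mlwa")
  df <- data.frame(wavelength_nm = lam, xi = exc$xi, c_abs_nm2 = exc$c_abs,
                   c_sca_nm2 = exc$c_sca, c_ext_nm2 = exc$c_ext,
                   gamma_rad_norm = em$gamma_rad, gamma_nr_norm = em$gamma_nr)
  f3 <- file.path(out_dir, "tabulated_backend_gold_ar1.5.csv")
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     f3, sep = ",", row.names = FALSE, quote = FALSE)
  files <- c(f1, f2, f3)
  data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
             row.names = NULL)
}
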