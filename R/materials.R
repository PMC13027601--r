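#' Optical material models
#'
#' A material model supplies the complex relative permittivity
#' \eqn{\varepsilon(\lambda) = \varepsilon' + i\varepsilon''} of a particle
#' metal at any wavelength, either by linear interpolation of a tabulated
#' dataset or by evaluating an analytic Drude-Lorentz sum. All materials are
#' treated as non-magnetic (\eqn{\mu = 1}).
#'
#' @param name Label for the material (e.g. `"gold"`).
#' @param table Data frame with columns `wavelength_nm`, `eps_re`, `eps_im`,
#'   strictly increasing in wavelength, with `eps_im >= 0` everywhere
#'   (passive material).
#' @param dl_params List of Drude-Lorentz parameters: `eps_inf`, plasma
#'   energy `wp_ev` (eV), Drude oscillator strength `f0` and damping
#'   `gamma0_ev` (eV), and `oscillators`, a list of `c(f, gamma_ev, w_ev)`
#'   Lorentz terms. Exactly one of `table` / `dl_params` must be given.
#' @return An object of class `mef_material`.
#' @seealso [permittivity()], [load_material_csv()], [mef_material()]
#' @export
material_model <- function(name, table = NULL, dl_params = NULL) {
  if (is.null(table) == is.null(dl_params)) {
    stop("supply exactly one of `table` or `dl_params`")
  }
  if (!is.null(table)) {
    req <- c("wavelength_nm", "eps_re", "eps_im")
    if (!all(req %in% names(table))) {
      stop("material table needs columns: ", paste(req, collapse = ", "))
    }
    table <- as.data.frame(table)[req]
    if (any(!is.finite(as.matrix(table)))) stop("non-finite entries in material table")
    if (any(diff(table$wavelength_nm) <= 0)) {
      stop("material table wavelengths must be strictly increasing")
    }
    if (any(table$eps_im < 0)) {
      stop("eps_im < 0 in material table: material must be passive")
    }
    source <- "tabulated"
  } else {
    stopifnot(is.list(dl_params),
              all(c("wp_ev", "f0", "gamma0_ev") %in% names(dl_params)))
    source <- "drude_lorentz"
  }
  structure(list(name = name, source = source, table = table,
                 dl_params = dl_params),
            class = "mef_material")
}

#' @export
print.mef_material <- function(x, ...) {
  cat("<mef_material>", x$name, "-", x$source, "\n")
  if (x$source == "tabulated") {
    cat("  ", nrow(x$table), "nodes,",
        sprintf("%.1f-%.1f nm", min(x$table$wavelength_nm), max(x$table$wavelength_nm)), "\n")
  }
  invisible(x)
}

#' Host medium
#'
#' Non-absorbing homogeneous host (default water, n = 1.33). The imaginary
#' part of the refractive index is identically zero by construction.
#'
#' @param refractive_index Real refractive index, > 0.
#' @return An object of class `mef_medium`.
#' @export
medium <- function(refractive_index = 1.33) {
  if (!is.numeric(refractive_index) || length(refractive_index) != 1 ||
      !is.finite(refractive_index) || refractive_index <= 0) {
    stop("refractive_index must be a single positive number")
  }
  structure(list(refractive_index = refractive_index,
                 eps = refractive_index^2),
            class = "mef_medium")
}

#' Complex relative permittivity at given wavelengths
#'
#' Tabulated materials are interpolated linearly in the complex permittivity
#' versus wavelength (linear interpolation of non-negative \eqn{\varepsilon''}
#' values cannot produce gain, unlike spline interpolation of n,k).
#' Drude-Lorentz materials are evaluated analytically,
#' \deqn{\varepsilon(E) = \varepsilon_\infty
#'   - \frac{f_0\,\omega_p^2}{E(E + i\Gamma_0)}
#'   + \sum_j \frac{f_j\,\omega_p^2}{(\omega_j^2 - E^2) - iE\Gamma_j}.}
#'
#' @param material A [material_model()].
#' @param wavelength Wavelengths in nm (vectorized).
#' @return Complex vector of relative permittivities.
#' @export
permittivity <- function(material, wavelength) {
  stopifnot(inherits(material, "mef_material"))
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("wavelengths must be positive and finite")
  }
  if (material$source == "tabulated") {
    tab <- material$table
    lo <- min(tab$wavelength_nm); hi <- max(tab$wavelength_nm)
    if (any(wavelength < lo) || any(wavelength > hi)) {
      stop(sprintf(
        "wavelength out of range for material '%s': table spans %.2f-%.2f nm",
        material$name, lo, hi))
    }
    complex(
      real = stats::approx(tab$wavelength_nm, tab$eps_re, wavelength)$y,
      imaginary = stats::approx(tab$wavelength_nm, tab$eps_im, wavelength)$y)
  } else {
    p <- material$dl_params
    E <- 1239.84193 / wavelength
    eps_inf <- if (is.null(p$eps_inf)) 1 else p$eps_inf
    eps <- eps_inf - p$f0 * p$wp_ev^2 / (E * (E + 1i * p$gamma0_ev))
    for (o in p$oscillators) {
      eps <- eps + o[1] * p$wp_ev^2 / ((o[3]^2 - E^2) - 1i * E * o[2])
    }
    eps
  }
}

#' Load a material table from CSV
#'
#' Accepts either the permittivity dialect (`wavelength_nm, eps_re, eps_im`)
#' or the refractive-index dialect (`wavelength_nm, n, k`), the latter
#' converted through \eqn{\varepsilon = (n + ik)^2}.
#'
#' @param path CSV file path.
#' @param name Material label; defaults to the file base name.
#' @return A tabulated [material_model()].
#' @export
load_material_csv <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  df <- utils::read.csv(path, check.names = TRUE)
  if (all(c("wavelength_nm", "eps_re", "eps_im") %in% names(df))) {
    tab <- df[c("wavelength_nm", "eps_re", "eps_im")]
  } else if (all(c("wavelength_nm", "n", "k") %in% names(df))) {
    if (any(df$k < 0)) stop("negative extinction coefficient k in ", path)
    tab <- data.frame(wavelength_nm = df$wavelength_nm,
                      eps_re = df$n^2 - df$k^2,
                      eps_im = 2 * df$n * df$k)
  } else {
    stop("CSV must have columns (wavelength_nm, eps_re, eps_im) or (wavelength_nm, n, k): ",
         path)
  }
  material_model(name, table = tab)
}

#' Export a material table to CSV (permittivity dialect)
#'
#' @param material A tabulated [material_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_csv <- function(material, path) {
  stopifnot(inherits(material, "mef_material"), material$source == "tabulated")
  utils::write.csv(
    format(material$table, digits = 15, trim = TRUE, scientific = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Vendored metal optical constants
#'
#' Experimental room-temperature optical constants of evaporated gold and
#' silver films (Johnson and Christy, Phys. Rev. B 6, 4370, 1972), shipped
#' as n,k tables covering roughly 354-984 nm and converted to permittivity
#' at load time. These are the defaults for all plasmonic calculations;
#' alternative datasets can be substituted through [load_material_csv()].
#'
#' @param name `"gold"` or `"silver"`.
#' @return A tabulated [material_model()].
#' @export
mef_material <- function(name = c("gold", "silver")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, "_jc1972.csv"), package = "mefopt",
                   mustWork = TRUE)
  load_material_csv(f, name = name)
}

#' Analytic Drude-Lorentz fits for gold and silver
#'
#' Lorentz-Drude parameterizations of bulk gold and silver optical constants
#' (Rakic et al., Appl. Opt. 37, 5271, 1998). These are independent of the
#' vendored experimental tables and serve as a cross-check; tabulated and
#' fitted permittivities of noble metals typically differ by 5-20% in the
#' interband region.
#'
#' @param name `"gold"` or `"silver"`.
#' @return A Drude-Lorentz [material_model()].
#' @export
drude_lorentz_material <- function(name = c("gold", "silver")) {
  name <- match.arg(name)
  p <- switch(name,
    gold = list(wp_ev = 9.03, f0 = 0.760, gamma0_ev = 0.053, oscillators = list(
      c(0.024, 0.241, 0.415), c(0.010, 0.345, 0.830), c(0.071, 0.870, 2.969),
      c(0.601, 2.494, 4.304), c(4.384, 2.214, 13.32))),
    silver = list(wp_ev = 9.01, f0 = 0.845, gamma0_ev = 0.048, oscillators = list(
      c(0.065, 3.886, 0.816), c(0.124, 0.452, 4.481), c(0.011, 0.065, 8.185),
      c(0.840, 0.916, 9.083), c(5.646, 2.419, 20.29))))
  material_model(paste0(name, "_dl"), dl_params = p)
}
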