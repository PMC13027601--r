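#' Nanorod geometry
#'
#' A nanorod is a cylinder of diameter `d` with hemispherical end caps; its
#' aspect ratio AR is the total length L (caps included) over `d`, so
#' AR = 1 is exactly a sphere of diameter `d`. For the semi-analytic rod
#' backend the particle is replaced by a prolate spheroid of the same
#' diameter; `mapping` selects how the spheroid length is chosen:
#' `"volume"` (default) preserves the capped-cylinder volume, giving an
#' effective spheroid aspect ratio `1.5 * AR - 0.5`, while `"length"`
#' preserves the total length L. Volume matching keeps the particle's
#' dipole strength and compensates the systematic blue bias of an
#' equal-length spheroid relative to a capped cylinder.
#'
#' @param d Cylinder diameter in nm, > 0.
#' @param ar Aspect ratio, >= 1.
#' @param mapping Spheroid surrogate mapping, `"volume"` or `"length"`.
#' @return An object of class `nanorod_geometry` with derived length
#'   `L = ar * d` and spheroid semi-axes `semi_major`, `semi_minor`.
#' @export
nanorod_geometry <- function(d, ar, mapping = c("volume", "length")) {
  mapping <- match.arg(mapping)
  if (!is.numeric(d) || d <= 0) stop("diameter d must be > 0")
  if (!is.numeric(ar) || ar < 1) stop("aspect ratio must be >= 1")
  ar_eff <- switch(mapping, volume = 1.5 * ar - 0.5, length = ar)
  structure(list(d = d, ar = ar, L = ar * d, cap_style = "hemispherical",
                 mapping = mapping, ar_eff = ar_eff,
                 semi_major = ar_eff * d / 2, semi_minor = d / 2),
            class = "nanorod_geometry")
}

#' @export
print.nanorod_geometry <- function(x, ...) {
  cat(sprintf("<nanorod_geometry> d = %g nm, AR = %g (L = %g nm), %s caps, %s-mapped spheroid (AR_eff = %g)\n",
              x$d, x$ar, x$L, x$cap_style, x$mapping, x$ar_eff))
  invisible(x)
}

#' Emitter placement relative to the particle
#'
#' The fluorophore sits on the particle's long axis at a gap `gap` (nm)
#' from the cap apex, outside the metal. `"perpendicular"` orientation
#' means the transition dipole is normal to the cap surface, i.e. along
#' the long axis - the configuration that couples to the longitudinal
#' plasmon; `"parallel"` is the transverse orientation.
#'
#' @param gap Surface-to-molecule distance in nm, > 0.
#' @param orientation Dipole orientation.
#' @return An object of class `emitter_placement`.
#' @export
emitter_placement <- function(gap, orientation = c("perpendicular", "parallel")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(gap) || length(gap) != 1 || !is.finite(gap) || gap <= 0) {
    stop("gap must be a single positive number (molecule outside the metal)")
  }
  if (gap < 1) {
    warning("gap < 1 nm: the quasistatic dipole surrogate degrades at sub-nm gaps")
  }
  structure(list(gap = gap, orientation = orientation),
            class = "emitter_placement")
}

# ---------------------------------------------------------------------------
# Spheroid MLWA machinery

# Depolarization factor along the long axis of a prolate spheroid.
prolate_depolarization <- function(ar_eff) {
  if (ar_eff == 1) return(1 / 3)
  e2 <- 1 - 1 / ar_eff^2
  e <- sqrt(e2)
  ((1 - e2) / e2) * (-1 + log((1 + e) / (1 - e)) / (2 * e))
}

# Longitudinal polarizability (volume convention: C_ext = k Im alpha) of the
# surrogate spheroid with modified-long-wavelength corrections: dynamic
# depolarization (k^2 term, scaled by the semi-axis along the field) and
# radiative reaction (i k^3 term, which guarantees C_abs >= 0). Vectorized
# over eps/k.
spheroid_polarizability <- function(eps, eps_m, geometry,
                                    axis = c("major", "minor"), k) {
  axis <- match.arg(axis)
  cc <- geometry$semi_major
  b <- geometry$semi_minor
  L1 <- prolate_depolarization(geometry$ar_eff)
  Lax <- if (axis == "major") L1 else (1 - L1) / 2
  lax <- if (axis == "major") cc else b
  V <- 4 * pi / 3 * cc * b^2
  a0 <- V * (eps - eps_m) / (eps_m + Lax * (eps - eps_m))
  a0 / (1 - k^2 / (4 * pi * lax) * a0 - 1i * k^3 / (6 * pi) * a0)
}

# Retarded near-zone coupling factor between a point at distance r on the
# long axis and a co-axial dipole at the particle center: E_axial =
# g(r) p / (eps0 eps_m). Includes the induction term (1 - i k r).
axial_coupling <- function(k, r) {
  2 / (4 * pi * r^3) * (1 - 1i * k * r) * exp(1i * k * r)
}
transverse_coupling <- function(k, r) {
  -1 / (4 * pi * r^3) * (1 - 1i * k * r - k^2 * r^2) * exp(1i * k * r)
}

# ---------------------------------------------------------------------------
# Backend implementations. A backend is a list with fields
#   name, ar_range = c(lo, hi), orientations,
#   excitation(geometry, material, medium, placement, wavelength) and
#   emission(geometry, material, medium, placement, wavelength),
# both vectorized over wavelength and returning data frames.

backend_mie_sphere <- function() {
  excitation <- function(geometry, material, medium, placement, wavelength) {
    eps_m <- medium$eps
    eps <- permittivity(material, wavelength)
    k <- 2 * pi * medium$refractive_index / wavelength
    a <- geometry$d / 2
    r <- a + placement$gap
    out <- t(vapply(seq_along(wavelength), function(i) {
      m <- sqrt(eps[i] / eps_m)
      xs <- mie_cross_sections(m, k[i] * a, k[i])
      xi <- mie_xi_axis(m, k[i] * a, k[i] * r)
      c(xi, xs)
    }, numeric(4)))
    data.frame(wavelength = wavelength, xi = unname(out[, 1]),
               c_abs = unname(out[, 2]), c_sca = unname(out[, 3]),
               c_ext = unname(out[, 4]))
  }
  emission <- function(geometry, material, medium, placement, wavelength) {
    eps_m <- medium$eps
    eps <- permittivity(material, wavelength)
    k <- 2 * pi * medium$refractive_index / wavelength
    a <- geometry$d / 2
    r <- a + placement$gap
    out <- t(vapply(seq_along(wavelength), function(i) {
      m <- sqrt(eps[i] / eps_m)
      mie_dipole_rates(m, k[i] * a, k[i] * r,
                       orientation = placement$orientation)[1:2]
    }, numeric(2)))
    data.frame(wavelength = wavelength, gamma_rad = unname(out[, 1]),
               gamma_nr = unname(out[, 2]))
  }
  list(name = "mie_sphere", ar_range = c(1, 1),
       orientations = c("perpendicular", "parallel"),
       excitation = excitation, emission = emission)
}

backend_spheroid_mlwa <- function() {
  fields <- function(geometry, material, medium, placement, wavelength) {
    eps_m <- medium$eps
    eps <- permittivity(material, wavelength)
    k <- 2 * pi * medium$refractive_index / wavelength
    r <- geometry$semi_major + placement$gap
    axis <- if (placement$orientation == "perpendicular") "major" else "minor"
    alpha <- spheroid_polarizability(eps, eps_m, geometry, axis = axis, k = k)
    g <- if (placement$orientation == "perpendicular") {
      axial_coupling(k, r)
    } else {
      transverse_coupling(k, r)
    }
    list(alpha = alpha, alpha_exc = spheroid_polarizability(
           eps, eps_m, geometry, axis = "major", k = k),
         g = g, k = k, r = r)
  }
  excitation <- function(geometry, material, medium, placement, wavelength) {
    f <- fields(geometry, material, medium, placement, wavelength)
    # plane wave polarized along the long axis (longitudinal LSPR); the
    # molecule is on the long axis, so the relevant coupling is axial
    c_ext <- f$k * Im(f$alpha_exc)
    c_sca <- f$k^4 / (6 * pi) * Mod(f$alpha_exc)^2
    xi <- Mod(1 + f$alpha_exc * axial_coupling(f$k, f$r))^2
    data.frame(wavelength = wavelength, xi = xi, c_abs = c_ext - c_sca,
               c_sca = c_sca, c_ext = c_ext)
  }
  emission <- function(geometry, material, medium, placement, wavelength) {
    f <- fields(geometry, material, medium, placement, wavelength)
    G <- f$alpha * f$g
    gamma_rad <- Mod(1 + G)^2
    im_alpha_abs <- Im(f$alpha) - f$k^3 / (6 * pi) * Mod(f$alpha)^2
    gamma_nr <- 6 * pi / f$k^3 * im_alpha_abs * Mod(f$g)^2
    data.frame(wavelength = wavelength, gamma_rad = gamma_rad,
               gamma_nr = pmax(gamma_nr, 0))
  }
  list(name = "spheroid_mlwa", ar_range = c(1, Inf),
       orientations = c("perpendicular", "parallel"),
       excitation = excitation, emission = emission)
}

# ---------------------------------------------------------------------------
# Registry

the_backends <- new.env(parent = emptyenv())

#' Register an electromagnetic backend
#'
#' A backend bundles an excitation solver (near-field enhancement and
#' cross-sections under plane-wave illumination) and an emission solver
#' (normalized radiative/non-radiative rates of a dipole near the particle)
#' behind one contract, so externally computed responses (e.g. exported
#' full-wave solver tables) can stand in for the analytic models.
#'
#' @param name Unique backend name.
#' @param backend List with fields `ar_range` (length 2), `orientations`,
#'   and vectorized functions
#'   `excitation(geometry, material, medium, placement, wavelength)` and
#'   `emission(geometry, material, medium, placement, wavelength)`.
#' @param overwrite Allow replacing an existing backend of the same name.
#' @return The backend name, invisibly.
#' @export
register_backend <- function(name, backend, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!overwrite && exists(name, envir = the_backends)) {
    stop("backend '", name, "' is already registered")
  }
  req <- c("ar_range", "orientations", "excitation", "emission")
  if (!all(req %in% names(backend))) {
    stop("backend must provide: ", paste(req, collapse = ", "))
  }
  backend$name <- name
  assign(name, backend, envir = the_backends)
  invisible(name)
}

#' List registered backend names
#' @return Character vector.
#' @export
list_backends <- function() sort(ls(envir = the_backends))

get_backend <- function(name) {
  if (!exists(name, envir = the_backends)) {
    stop("unknown backend '", name, "'; registered: ",
         paste(list_backends(), collapse = ", "))
  }
  get(name, envir = the_backends)
}

# Default dispatch: exact Mie for spheres, spheroid surrogate for rods.
select_backend <- function(geometry, backend = NULL) {
  if (!is.null(backend)) {
    b <- if (is.character(backend)) get_backend(backend) else backend
  } else {
    b <- if (geometry$ar == 1) get_backend("mie_sphere") else get_backend("spheroid_mlwa")
  }
  if (geometry$ar < b$ar_range[1] || geometry$ar > b$ar_range[2]) {
    stop(sprintf("backend '%s' supports AR in [%g, %g], requested AR = %g",
                 b$name, b$ar_range[1], b$ar_range[2], geometry$ar))
  }
  b
}

#' Excitation-side response of the particle
#'
#' For a plane wave polarized along the particle's long axis, returns the
#' near-field intensity enhancement \eqn{\xi = |E|^2/|E_0|^2} at the
#' molecule position (on the long axis, `gap` nm beyond the cap apex) and
#' the absorption, scattering, and extinction cross-sections, per
#' wavelength.
#'
#' @param geometry A [nanorod_geometry()].
#' @param material A [material_model()].
#' @param medium A [medium()].
#' @param placement An [emitter_placement()].
#' @param wavelength Wavelengths in nm (vectorized).
#' @param backend Backend name or object; default dispatch is exact Mie for
#'   AR = 1 and the MLWA spheroid surrogate for AR > 1.
#' @return Data frame of class `excitation_result` with columns
#'   `wavelength`, `xi`, `c_abs`, `c_sca`, `c_ext` (cross-sections in nm^2).
#' @export
excitation_response <- function(geometry, material, medium, placement,
                                wavelength, backend = NULL) {
  b <- select_backend(geometry, backend)
  out <- b$excitation(geometry, material, medium, placement, wavelength)
  class(out) <- c("excitation_result", class(out))
  attr(out, "backend") <- b$name
  out
}

#' Emission-side response: normalized dipole decay rates
#'
#' Radiative and non-radiative relaxation rates of the
#' particle-fluorophore complex, both normalized to the radiative rate of
#' the isolated molecule in the same host medium, per wavelength. As the
#' gap grows, `gamma_rad -> 1` and `gamma_nr -> 0`.
#'
#' @inheritParams excitation_response
#' @return Data frame of class `emission_rates` with columns `wavelength`,
#'   `gamma_rad`, `gamma_nr`.
#' @export
emission_response <- function(geometry, material, medium, placement,
                              wavelength, backend = NULL) {
  b <- select_backend(geometry, backend)
  if (!(placement$orientation %in% b$orientations)) {
    stop("backend '", b$name, "' does not support orientation '",
         placement$orientation, "'")
  }
  out <- b$emission(geometry, material, medium, placement, wavelength)
  class(out) <- c("emission_rates", class(out))
  attr(out, "backend") <- b$name
  out
}

#' Tabulated backend from a solver-exported CSV
#'
#' Reads precomputed per-wavelength responses (columns `wavelength_nm, xi,
#' c_abs_nm2, c_sca_nm2, c_ext_nm2, gamma_rad_norm, gamma_nr_norm`) as
#' exported from any external electromagnetic solver, and serves them under
#' the standard backend contract; queries between rows are interpolated
#' linearly in every quantity.
#'
#' @param path CSV file path.
#' @param ar_range Aspect-ratio range the table is valid for.
#' @param orientations Supported dipole orientations.
#' @return A backend list suitable for [register_backend()].
#' @export
tabulated_backend <- function(path, ar_range = c(1, Inf),
                              orientations = c("perpendicular", "parallel")) {
  df <- utils::read.csv(path)
  req <- c("wavelength_nm", "xi", "c_abs_nm2", "c_sca_nm2", "c_ext_nm2",
           "gamma_rad_norm", "gamma_nr_norm")
  if (!all(req %in% names(df))) {
    stop("tabulated backend CSV must have columns: ", paste(req, collapse = ", "))
  }
  if (any(diff(df$wavelength_nm) <= 0)) {
    stop("tabulated backend wavelengths must be strictly increasing")
  }
  look <- function(col, wavelength) {
    rng <- range(df$wavelength_nm)
    if (any(wavelength < rng[1]) || any(wavelength > rng[2])) {
      stop(sprintf("wavelength outside tabulated span %.2f-%.2f nm", rng[1], rng[2]))
    }
    stats::approx(df$wavelength_nm, df[[col]], wavelength)$y
  }
  list(
    name = "tabulated", ar_range = ar_range, orientations = orientations,
    excitation = function(geometry, material, medium, placement, wavelength) {
      data.frame(wavelength = wavelength,
                 xi = look("xi", wavelength),
                 c_abs = look("c_abs_nm2", wavelength),
                 c_sca = look("c_sca_nm2", wavelength),
                 c_ext = look("c_ext_nm2", wavelength))
    },
    emission = function(geometry, material, medium, placement, wavelength) {
      data.frame(wavelength = wavelength,
                 gamma_rad = look("gamma_rad_norm", wavelength),
                 gamma_nr = look("gamma_nr_norm", wavelength))
    })
}
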