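# Fluorescence enhancement quantities. Two descriptions are implemented:
#
#   TM (traditional monochromatic): the fluorophore is reduced to its two
#   spectral peaks. The enhancement factor is K_flu = xi(lambda_ex) *
#   Y(lambda_em) with Y = G_rad / (G_rad + G_nr + 1/Y0 - 1) built from the
#   unweighted normalized rates.
#
#   RM (refined, spectrally weighted): the excitation spectrum weights the
#   near field, xi_eff = I_ex * xi, and the emission spectrum weights both
#   decay rates, G_rad_eff = I_em * G_rad, G_nr_eff = I_em * G_nr. The
#   effective yield Y_eff and enhancement K_flu_eff = xi_eff * Y_eff then
#   live only where the molecule actually absorbs and emits. The photon
#   energy factors in the dimensional rate definitions cancel in the
#   normalized ratios and re-enter only in the integral criterion.

#' Spectrally weighted field enhancement
#'
#' \eqn{\xi_{eff} = I_{ex}\,\xi}: the near-field intensity enhancement at
#' the molecule, weighted by its normalized excitation spectrum.
#'
#' @param xi Field intensity enhancement, >= 0 (vectorized).
#' @param I_ex Normalized excitation intensity in \[0, 1\].
#' @return `xi * I_ex`.
#' @export
xi_eff <- function(xi, I_ex) {
  if (any(xi < 0) || any(I_ex < 0)) stop("xi and I_ex must be non-negative")
  if (any(I_ex > 1)) stop("I_ex must be normalized to [0, 1]")
  xi * I_ex
}

#' Spectrally weighted decay rates
#'
#' Scales both normalized rates by the normalized emission intensity.
#'
#' @param rates Data frame with `gamma_rad`, `gamma_nr` (an
#'   `emission_rates` result).
#' @param I_em Normalized emission intensity in \[0, 1\] (vectorized).
#' @return List with `gamma_rad_eff`, `gamma_nr_eff`.
#' @export
effective_rates <- function(rates, I_em) {
  if (any(I_em < 0) || any(I_em > 1)) stop("I_em must lie in [0, 1]")
  list(gamma_rad_eff = rates$gamma_rad * I_em,
       gamma_nr_eff = rates$gamma_nr * I_em)
}

#' Modified quantum yield
#'
#' \deqn{Y = \frac{\Gamma_{rad}}{\Gamma_{rad} + \Gamma_{nr} + 1/Y_0 - 1}}
#' with rates normalized to the isolated molecule's radiative rate. The
#' same formula serves the monochromatic yield (unweighted rates) and the
#' effective yield (emission-weighted rates). When both rates vanish and
#' `Y0 = 1` (a 0/0 outside the emission band) the yield is 0 by convention:
#' no emission there.
#'
#' @param gamma_rad,gamma_nr Normalized (possibly emission-weighted) rates,
#'   >= 0, vectorized.
#' @param Y0 Intrinsic quantum yield in (0, 1].
#' @return Yield values in \[0, 1\].
#' @export
quantum_yield_eff <- function(gamma_rad, gamma_nr, Y0) {
  if (!(Y0 > 0 && Y0 <= 1)) stop("Y0 must lie in (0, 1]")
  if (any(gamma_rad < 0) || any(gamma_nr < 0)) stop("rates must be >= 0")
  den <- gamma_rad + gamma_nr + 1 / Y0 - 1
  y <- ifelse(den > 0, gamma_rad / den, 0)
  pmin(pmax(y, 0), 1)
}

#' Fluorescence enhancement factor
#'
#' \eqn{K = \xi \cdot Y}: product of the (possibly spectrally weighted)
#' field enhancement at the excitation wavelength and the (possibly
#' effective) quantum yield.
#'
#' @param xi_exc Field enhancement at the chosen excitation wavelength, >= 0.
#' @param Y Quantum yield (vectorized over emission wavelength).
#' @return `xi_exc * Y`.
#' @export
k_flu_eff <- function(xi_exc, Y) {
  if (any(xi_exc < 0) || any(Y < 0)) stop("inputs must be non-negative")
  xi_exc * Y
}

#' Monochromatic (TM) fluorescence quantities
#'
#' Evaluates the traditional description: the excitation side is frozen at
#' the excitation peak \eqn{\lambda_{ex}} and the emission side at the
#' emission peak \eqn{\lambda_{em}} of the fluorophore. Per-wavelength
#' curves are also returned for inspection; the scalar `K_flu` is
#' \eqn{\xi(\lambda_{ex})\,Y(\lambda_{em})}.
#'
#' @param excitation An `excitation_result` covering \eqn{\lambda_{ex}}.
#' @param rates An `emission_rates` covering \eqn{\lambda_{em}}.
#' @param spectra A [fluorophore_spectra()] (supplies the two peak
#'   wavelengths and `Y0`).
#' @return An object of class `mef_result` (model `"TM"`) with
#'   per-wavelength `xi`, `gamma_rad`, `gamma_nr`, `Y`, `K_flu` curves and
#'   scalars `K_flu`, `xi_at_exc`, `Y_at_em`, `lambda_exc`, `lambda_em`,
#'   plus the free-space baseline `Y0` (K of the isolated molecule in this
#'   normalization) and the fold enhancement `K_flu / Y0`.
#' @export
tm_quantities <- function(excitation, rates, spectra) {
  stopifnot(identical(excitation$wavelength, rates$wavelength))
  lam <- excitation$wavelength
  Y0 <- spectra$Y0
  lam_ex <- spectra$lambda_ex_peak
  lam_em <- spectra$lambda_em_peak
  Y <- quantum_yield_eff(rates$gamma_rad, rates$gamma_nr, Y0)
  # peaks outside the solver grid evaluate at the nearest grid edge
  xi_exc <- stats::approx(lam, excitation$xi, lam_ex, rule = 2)$y
  Y_em <- stats::approx(lam, Y, lam_em, rule = 2)$y
  K <- k_flu_eff(xi_exc, Y_em)
  structure(list(
    model = "TM", wavelength = lam,
    xi = excitation$xi,
    gamma_rad = rates$gamma_rad, gamma_nr = rates$gamma_nr,
    Y = Y, K_curve = k_flu_eff(xi_exc, Y),
    lambda_exc = lam_ex, lambda_em = lam_em,
    xi_at_exc = xi_exc, Y_at_em = Y_em,
    K_flu = K, Y0 = Y0, fold_enhancement = K / Y0),
    class = "mef_result")
}

#' Spectrally refined (RM) fluorescence quantities
#'
#' Evaluates the refined description on a wavelength grid: weighted field
#' enhancement `xi_eff`, weighted rates, effective yield `Y_eff`, and the
#' enhancement curve `K_flu_eff(lambda) = xi_eff(lambda_exc) *
#' Y_eff(lambda)`. The excitation wavelength defaults to the argmax of
#' `xi_eff` (refined by parabolic interpolation onto the grid node), and
#' can be overridden.
#'
#' @inheritParams tm_quantities
#' @param lambda_exc Optional fixed excitation wavelength in nm; `NULL`
#'   selects the maximum of `xi_eff`.
#' @return An object of class `mef_result` (model `"RM"`) with
#'   per-wavelength `xi_eff`, `gamma_rad_eff`, `gamma_nr_eff`, `Y_eff`,
#'   `K_curve`, scalars `K_flu_eff` (max of the curve over the emission
#'   range), `K_at_em_peak`, `lambda_exc`, `integral_criterion`-ready
#'   curves, and the `Y0` baseline.
#' @export
rm_quantities <- function(excitation, rates, spectra, lambda_exc = NULL) {
  stopifnot(identical(excitation$wavelength, rates$wavelength))
  lam <- excitation$wavelength
  Y0 <- spectra$Y0
  I_ex <- interp_spectra(spectra, lam, "ex")
  I_em <- interp_spectra(spectra, lam, "em")
  xe <- xi_eff(excitation$xi, I_ex)
  eff <- effective_rates(rates, I_em)
  Y_eff <- quantum_yield_eff(eff$gamma_rad_eff, eff$gamma_nr_eff, Y0)
  if (is.null(lambda_exc)) {
    pk <- refine_peak(lam, xe)
    lambda_exc <- pk$lambda
    xi_exc <- pk$value
  } else {
    xi_exc <- stats::approx(lam, xe, lambda_exc, rule = 2)$y
  }
  K_curve <- k_flu_eff(xi_exc, Y_eff)
  K_at_em <- stats::approx(lam, K_curve, spectra$lambda_em_peak, rule = 2)$y
  structure(list(
    model = "RM", wavelength = lam,
    xi_eff = xe, gamma_rad_eff = eff$gamma_rad_eff,
    gamma_nr_eff = eff$gamma_nr_eff, Y_eff = Y_eff, K_curve = K_curve,
    lambda_exc = lambda_exc, lambda_em = spectra$lambda_em_peak,
    xi_at_exc = xi_exc, K_at_em_peak = K_at_em,
    K_flu_eff = max(K_curve), Y0 = Y0,
    fold_enhancement = max(K_curve) / Y0),
    class = "mef_result")
}

#' @export
print.mef_result <- function(x, ...) {
  if (x$model == "TM") {
    cat(sprintf("<mef_result TM> K_flu = %.3g (xi = %.3g at %.1f nm, Y = %.3g at %.1f nm)\n",
                x$K_flu, x$xi_at_exc, x$lambda_exc, x$Y_at_em, x$lambda_em))
  } else {
    cat(sprintf("<mef_result RM> K_flu_eff = %.3g (xi_eff = %.3g at %.1f nm; K = %.3g at em peak %.1f nm)\n",
                x$K_flu_eff, x$xi_at_exc, x$lambda_exc, x$K_at_em_peak, x$lambda_em))
  }
  invisible(x)
}

#' Integral total-power criterion
#'
#' Estimates the gain of the total emitted power for a refined-model
#' result: the trapezoidal integral of \eqn{\Gamma_{rad,eff}(\lambda)}
#' over the fluorophore emission support, weighted by the relative photon
#' energy \eqn{\lambda_{em}/\lambda}, multiplied by the maximum of
#' \eqn{\xi_{eff}}.
#'
#' @param mef An RM [rm_quantities()] result.
#' @param spectra The [fluorophore_spectra()] used to build it.
#' @param photon_weight Apply the photon-energy weight (default `TRUE`).
#' @return Scalar criterion value (0, with a warning, if the emission
#'   support does not intersect the grid).
#' @export
integral_criterion <- function(mef, spectra, photon_weight = TRUE) {
  stopifnot(inherits(mef, "mef_result"))
  if (mef$model != "RM") stop("integral_criterion needs an RM result")
  lam <- mef$wavelength
  I_em <- interp_spectra(spectra, lam, "em")
  sel <- I_em > 0
  if (sum(sel) < 2) {
    warning("emission support does not intersect the wavelength grid")
    return(0)
  }
  w <- if (photon_weight) spectra$lambda_em_peak / lam[sel] else rep(1, sum(sel))
  trapz(lam[sel], mef$gamma_rad_eff[sel] * w) * max(mef$xi_eff)
}
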