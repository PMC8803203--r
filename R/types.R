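#' Diffuse reflectance/transmittance measurement
#'
#' Container for one calibrated integrating-sphere measurement: the diffuse
#' reflectance and transmittance fractions of a slab of known thickness,
#' together with the incident power and probe wavelength the measurement was
#' taken at.
#'
#' @param r_d Diffuse reflectance fraction, strictly in (0, 1).
#' @param t_d Diffuse transmittance fraction, strictly in (0, 1).
#' @param thickness_cm Slab optical thickness in cm (> 0).
#' @param power_mw Incident power in mW (metadata, optional).
#' @param wavelength_nm Probe wavelength in nm (metadata, default 808).
#'
#' @details `r_d + t_d < 1` is required for a physically invertible
#'   (absorbing) sample; equality is reached only in the zero-absorption
#'   limit. Values with `r_d + t_d > 1` are rejected at construction.
#'
#' @return An object of class `diffuse_measurement`.
#' @export
#' @examples
#' diffuse_measurement(r_d = 0.46, t_d = 0.45, thickness_cm = 0.1)
diffuse_measurement <- function(r_d, t_d, thickness_cm,
                                power_mw = NA_real_, wavelength_nm = 808) {
  if (!is.finite(r_d) || r_d <= 0 || r_d >= 1)
    stop_tl("r_d must lie strictly in (0, 1)", "tl_invalid_parameter")
  if (!is.finite(t_d) || t_d <= 0 || t_d >= 1)
    stop_tl("t_d must lie strictly in (0, 1)", "tl_invalid_parameter")
  if (!is.finite(thickness_cm) || thickness_cm <= 0)
    stop_tl("thickness_cm must be > 0", "tl_invalid_parameter")
  if (r_d + t_d > 1 + 1e-12)  # equality allowed: zero-absorption limit
    stop_tl(sprintf(
      "non-physical measurement: r_d + t_d = %.4f > 1 (more light out than in)",
      r_d + t_d), "tl_nonphysical_measurement")
  structure(
    list(r_d = r_d, t_d = t_d, thickness_cm = thickness_cm,
         power_mw = power_mw, wavelength_nm = wavelength_nm),
    class = "diffuse_measurement"
  )
}

#' @export
print.diffuse_measurement <- function(x, ...) {
  cat(sprintf(
    "<diffuse_measurement> R_d = %.4f, T_d = %.4f, D = %g cm, P = %s mW\n",
    x$r_d, x$t_d, x$thickness_cm,
    if (is.na(x$power_mw)) "?" else format(x$power_mw)))
  invisible(x)
}

#' Kubelka-Munk coefficients of diffuse radiation
#'
#' The two-flux scattering (`s_km`) and absorption (`a_km`) coefficients
#' together with the auxiliary parameters `x = 1 + a_km/s_km` and
#' `y = sqrt(x^2 - 1)` that appear in the closed-form slab solution.
#'
#' @param s_km Two-flux scattering coefficient of diffuse radiation (1/cm, > 0).
#' @param a_km Two-flux absorption coefficient of diffuse radiation (1/cm, >= 0).
#'
#' @return An object of class `km_coefficients` with fields `s_km`, `a_km`,
#'   `x`, `y`.
#' @export
#' @examples
#' km_coefficients(s_km = 10, a_km = 1)
km_coefficients <- function(s_km, a_km) {
  if (!is.finite(s_km) || s_km <= 0)
    stop_tl("s_km must be > 0", "tl_invalid_parameter")
  if (!is.finite(a_km) || a_km < 0)
    stop_tl("a_km must be >= 0", "tl_invalid_parameter")
  x <- 1 + a_km / s_km
  structure(
    list(s_km = s_km, a_km = a_km, x = x, y = sqrt(x^2 - 1)),
    class = "km_coefficients"
  )
}

#' @export
print.km_coefficients <- function(x, ...) {
  cat(sprintf("<km_coefficients> S = %.6g 1/cm, A = %.6g 1/cm (X = %.6g)\n",
              x$s_km, x$a_km, x$x))
  invisible(x)
}

#' Transport-level optical properties of a sample
#'
#' Absorption coefficient, reduced scattering coefficient and (optionally)
#' the anisotropy factor, scattering coefficient and refractive index of one
#' sample/condition. When both `g` and `mu_s` are given they must satisfy
#' `mu_s_prime = mu_s * (1 - g)`; when `g` alone is given, `mu_s` is filled
#' in from that similarity relation.
#'
#' @param mu_a Absorption coefficient (1/cm, >= 0).
#' @param mu_s_prime Reduced scattering coefficient (1/cm, >= 0).
#' @param thickness_cm Slab thickness in cm (> 0).
#' @param g Anisotropy factor in (-1, 1), optional.
#' @param mu_s Scattering coefficient (1/cm), optional.
#' @param refractive_index Relative refractive index (>= 1), default 1.
#' @param power_mw Incident power metadata, optional.
#'
#' @return An object of class `optical_properties`.
#' @export
#' @examples
#' optical_properties(mu_a = 0.5, mu_s_prime = 13.5, thickness_cm = 0.1, g = 0.9)
optical_properties <- function(mu_a, mu_s_prime, thickness_cm,
                               g = NA_real_, mu_s = NA_real_,
                               refractive_index = 1, power_mw = NA_real_) {
  if (!is.finite(mu_a) || mu_a < 0)
    stop_tl("mu_a must be >= 0", "tl_invalid_parameter")
  if (!is.finite(mu_s_prime) || mu_s_prime < 0)
    stop_tl("mu_s_prime must be >= 0", "tl_invalid_parameter")
  if (!is.finite(thickness_cm) || thickness_cm <= 0)
    stop_tl("thickness_cm must be > 0", "tl_invalid_parameter")
  if (!is.na(g)) {
    if (g <= -1 || g >= 1)
      stop_tl("g must lie strictly in (-1, 1)", "tl_invalid_parameter")
    if (is.na(mu_s)) {
      mu_s <- mu_s_prime / (1 - g)
    } else if (abs(mu_s * (1 - g) - mu_s_prime) >
               1e-12 * max(1, mu_s_prime)) {
      stop_tl("inconsistent (mu_s, g): mu_s_prime must equal mu_s*(1-g)",
              "tl_invalid_parameter")
    }
  }
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, thickness_cm = thickness_cm,
         g = g, mu_s = mu_s, refractive_index = refractive_index,
         power_mw = power_mw),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %.4g 1/cm, mu_s' = %.4g 1/cm, D = %g cm%s\n",
    x$mu_a, x$mu_s_prime, x$thickness_cm,
    if (is.na(x$g)) "" else sprintf(", g = %.3g", x$g)))
  invisible(x)
}
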