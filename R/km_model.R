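#' Forward Kubelka-Munk slab model
#'
#' Computes the diffuse reflectance and transmittance of a homogeneous slab
#' from the two-flux scattering and absorption coefficients, using the
#' hyperbolic closed form
#' \deqn{R_d = \sinh(S Y D) / (X \sinh(S Y D) + Y \cosh(S Y D))}
#' \deqn{T_d = Y / (X \sinh(S Y D) + Y \cosh(S Y D))}
#' with \eqn{X = 1 + A/S} and \eqn{Y = \sqrt{X^2 - 1}}. This is the unique
#' form consistent with the standard Kottler inversion implemented in
#' [invert_km()]: inversion of the forward output recovers the inputs
#' exactly. In the zero-absorption limit (A = 0) the expressions reduce to
#' \eqn{R_d = SD/(1+SD)}, \eqn{T_d = 1/(1+SD)}.
#'
#' @param s_km Two-flux scattering coefficient (1/cm, > 0).
#' @param a_km Two-flux absorption coefficient (1/cm, >= 0).
#' @param thickness_cm Slab thickness D (cm, > 0).
#'
#' @return A list with components `r_d` and `t_d`, each in (0, 1), with
#'   `r_d + t_d <= 1` (equality iff `a_km == 0`).
#' @seealso [invert_km()], [estimate_optical_properties()]
#' @export
#' @examples
#' forward_km(s_km = 10, a_km = 0, thickness_cm = 0.1)  # R = T = 1/2
forward_km <- function(s_km, a_km, thickness_cm) {
  if (!is.finite(s_km) || s_km <= 0)
    stop_tl("s_km must be > 0", "tl_invalid_parameter")
  if (!is.finite(a_km) || a_km < 0)
    stop_tl("a_km must be >= 0", "tl_invalid_parameter")
  if (!is.finite(thickness_cm) || thickness_cm <= 0)
    stop_tl("thickness_cm must be > 0", "tl_invalid_parameter")

  if (a_km == 0) {
    # zero-absorption limit of the hyperbolic form (0/0 otherwise)
    sd <- s_km * thickness_cm
    return(list(r_d = sd / (1 + sd), t_d = 1 / (1 + sd)))
  }
  x <- 1 + a_km / s_km
  y <- sqrt(x^2 - 1)
  syd <- s_km * y * thickness_cm
  if (syd > 350) {
    # asymptotic optically-thick branch: sinh ~ cosh ~ e^syd/2, exp overflows
    return(list(r_d = 1 / (x + y), t_d = 0))
  }
  den <- x * sinh(syd) + y * cosh(syd)
  list(r_d = sinh(syd) / den, t_d = y / den)
}

#' Invert the Kubelka-Munk model from measured diffuse fractions
#'
#' Recovers the two-flux scattering and absorption coefficients from a
#' measured diffuse reflectance/transmittance pair via the Kottler closed
#' form: \eqn{X = (1 + R_d^2 - T_d^2)/(2 R_d)}, \eqn{Y = \sqrt{X^2-1}},
#' \eqn{S = \ln[(1 - R_d(X-Y))/T_d]/(Y D)}, \eqn{A = (X-1) S}.
#'
#' @param m A [diffuse_measurement()].
#' @param zero_absorption_tol Treat `x - 1` below this as the zero-absorption
#'   limit and use the closed-form limit `s_km = r_d/(D (1 - r_d))`,
#'   `a_km = 0` (the general expressions are 0/0 there). Default `1e-8`.
#'
#' @return A [km_coefficients()] object.
#' @export
#' @examples
#' m <- diffuse_measurement(0.5, 0.5, thickness_cm = 0.1)
#' invert_km(m)  # s_km = 10, a_km = 0
invert_km <- function(m, zero_absorption_tol = 1e-8) {
  stopifnot(inherits(m, "diffuse_measurement"))
  r <- m$r_d; t <- m$t_d; D <- m$thickness_cm
  if (r + t >= 1 + 1e-15)
    stop_tl(sprintf("non-physical measurement: r_d + t_d = %.6f >= 1", r + t),
            "tl_nonphysical_measurement")
  x <- (1 + r^2 - t^2) / (2 * r)
  if (x < 1 - 1e-12)
    stop_tl("non-physical measurement: X < 1 (y imaginary)",
            "tl_nonphysical_measurement")
  if (x - 1 < zero_absorption_tol) {
    s <- r / (D * (1 - r))
    return(km_coefficients(s_km = s, a_km = 0))
  }
  y <- sqrt(x^2 - 1)
  s <- log((1 - r * (x - y)) / t) / (y * D)
  if (!is.finite(s) || s <= 0)
    stop_tl("inversion produced non-positive s_km (degenerate measurement)",
            "tl_nonphysical_measurement")
  km_coefficients(s_km = s, a_km = (x - 1) * s)
}

#' Convert Kubelka-Munk coefficients to transport coefficients
#'
#' Applies the two-flux/diffusion correspondence `a_km = 2 mu_a`,
#' `s_km = (3/4) mu_s' - (1/4) mu_a`, solved for the transport pair:
#' `mu_a = a_km / 2`, `mu_s' = (4 s_km + mu_a) / 3`.
#'
#' @param k A [km_coefficients()] object.
#' @param thickness_cm Slab thickness carried into the result (cm).
#' @param power_mw Optional incident-power metadata carried through.
#'
#' @return An [optical_properties()] object.
#' @export
km_to_transport <- function(k, thickness_cm = 0.1, power_mw = NA_real_) {
  stopifnot(inherits(k, "km_coefficients"))
  mu_a <- k$a_km / 2
  mu_s_prime <- (4 * k$s_km + mu_a) / 3
  optical_properties(mu_a = mu_a, mu_s_prime = mu_s_prime,
                     thickness_cm = thickness_cm, power_mw = power_mw)
}

#' Convert transport coefficients to Kubelka-Munk coefficients
#'
#' Forward direction of the correspondence used by [km_to_transport()]:
#' `a_km = 2 mu_a`, `s_km = 0.75 mu_s' - 0.25 mu_a`. The two-flux picture
#' assumes scattering-dominated diffuse radiance, so `mu_s' > mu_a / 3` is
#' required for a positive `s_km`.
#'
#' @param p An [optical_properties()] object.
#' @return A [km_coefficients()] object.
#' @export
transport_to_km <- function(p) {
  stopifnot(inherits(p, "optical_properties"))
  s_km <- 0.75 * p$mu_s_prime - 0.25 * p$mu_a
  if (s_km <= 0)
    stop_tl(sprintf(
      "Kubelka-Munk inapplicable: mu_s' = %g <= mu_a/3 = %g (model assumes scattering-dominated diffuse radiance)",
      p$mu_s_prime, p$mu_a / 3), "tl_km_inapplicable")
  km_coefficients(s_km = s_km, a_km = 2 * p$mu_a)
}

#' Optical penetration depth
#'
#' The 1/e depth of the fluence rate in the diffusion regime,
#' \eqn{\delta = 1/\sqrt{3 \mu_a (\mu_a + \mu_s')}}, i.e. the reciprocal of
#' the effective attenuation coefficient \eqn{\mu_{eff}} used by
#' [solve_fluence()]. At fixed `mu_a` the depth increases as `mu_s'`
#' decreases: fewer scattering events per unit length let light travel
#' deeper.
#'
#' @param p An [optical_properties()] object.
#' @return Penetration depth in cm. `mu_a = 0` returns `Inf` with a warning
#'   (the correct mathematical limit: nothing absorbs, light penetrates
#'   indefinitely).
#' @export
#' @examples
#' penetration_depth(optical_properties(0.5, 13.5, 0.1))  # 1/sqrt(21)
penetration_depth <- function(p) {
  stopifnot(inherits(p, "optical_properties"))
  if (p$mu_a == 0) {
    warning("mu_a = 0: penetration depth is infinite")
    return(Inf)
  }
  1 / sqrt(3 * p$mu_a * (p$mu_a + p$mu_s_prime))
}

# mu_eff = 1/delta; shared by penetration_depth and the fluence solver
effective_attenuation <- function(mu_a, mu_s_prime) {
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Estimate transport optical properties from one measurement
#'
#' Composition of [invert_km()] and [km_to_transport()]: inverts the
#' two-flux model from a calibrated diffuse reflectance/transmittance pair
#' and converts the result to the absorption and reduced scattering
#' coefficients, carrying the thickness and power metadata through.
#'
#' @param m A [diffuse_measurement()].
#' @return An [optical_properties()] object.
#' @export
#' @examples
#' m <- diffuse_measurement(0.46103, 0.44528, thickness_cm = 0.1)
#' estimate_optical_properties(m)  # mu_a ~ 0.5, mu_s' ~ 13.5
estimate_optical_properties <- function(m) {
  stopifnot(inherits(m, "diffuse_measurement"))
  km_to_transport(invert_km(m), thickness_cm = m$thickness_cm,
                  power_mw = m$power_mw)
}

#' Invert a table of diffuse fractions
#'
#' Vectorised front end over [estimate_optical_properties()] for a
#' data frame with columns `power_mw`, `r_d`, `t_d` and (optionally)
#' `thickness_cm`.
#'
#' @param rt A data frame with columns `power_mw`, `r_d`, `t_d`, and
#'   optionally `thickness_cm` and `replicate_id`.
#' @param thickness_cm Fallback thickness when the table has no
#'   `thickness_cm` column.
#'
#' @return A data frame with one row per input row: `power_mw`,
#'   `mu_a_cm1`, `mu_s_prime_cm1`, `s_km_cm1`, `a_km_cm1`,
#'   `penetration_depth_cm` (plus `replicate_id` when present).
#' @export
invert_rt_table <- function(rt, thickness_cm = NULL) {
  stopifnot(is.data.frame(rt), all(c("power_mw", "r_d", "t_d") %in% names(rt)))
  thick <- if ("thickness_cm" %in% names(rt)) rt$thickness_cm
           else if (!is.null(thickness_cm)) rep(thickness_cm, nrow(rt))
           else stop_tl("no thickness_cm column and no fallback given",
                        "tl_invalid_parameter")
  out <- lapply(seq_len(nrow(rt)), function(i) {
    m <- diffuse_measurement(rt$r_d[i], rt$t_d[i], thick[i],
                             power_mw = rt$power_mw[i])
    k <- invert_km(m)
    p <- km_to_transport(k, thickness_cm = thick[i], power_mw = rt$power_mw[i])
    delta <- if (p$mu_a == 0) Inf else 1 / effective_attenuation(p$mu_a, p$mu_s_prime)
    data.frame(power_mw = rt$power_mw[i],
               mu_a_cm1 = p$mu_a, mu_s_prime_cm1 = p$mu_s_prime,
               s_km_cm1 = k$s_km, a_km_cm1 = k$a_km,
               penetration_depth_cm = delta)
  })
  res <- do.call(rbind, out)
  if ("replicate_id" %in% names(rt)) res$replicate_id <- rt$replicate_id
  res
}
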