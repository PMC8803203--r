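#' Diffusion coefficient of the photon-diffusion approximation
#'
#' \eqn{D = 1 / (3 (\mu_a + \mu_s'))} in cm. Together with
#' \eqn{\mu_{eff} = \sqrt{\mu_a / D}} it fully parameterises the
#' steady-state diffusion equation solved by [solve_fluence()].
#'
#' @param p An [optical_properties()] object.
#' @return Diffusion coefficient in cm.
#' @export
#' @examples
#' diffusion_coefficient(optical_properties(0.5, 13.5, 0.1))  # 1/42
diffusion_coefficient <- function(p) {
  stopifnot(inherits(p, "optical_properties"))
  if (p$mu_a + p$mu_s_prime <= 0)
    stop_tl("mu_a + mu_s_prime must be > 0", "tl_invalid_parameter")
  1 / (3 * (p$mu_a + p$mu_s_prime))
}

#' Solve the steady-state diffusion equation on a square surface domain
#'
#' Solves \eqn{\mu_a \phi - \nabla \cdot (D \nabla \phi) = S} on a 2D
#' square domain with a point source at the centre (the laser spot on the
#' sample surface) and zero-fluence Dirichlet boundaries, by a five-point
#' finite-difference discretisation and a direct sparse solve. The source
#' is a single-node delta carrying total power `source_strength`.
#'
#' Away from the source and boundary the solution approaches the 2D
#' infinite-medium Green's function
#' \eqn{\phi(r) = S K_0(\mu_{eff} r) / (2 \pi D)}, which serves as the
#' analytic oracle in the test-suite. Two guards keep the discretisation
#' honest: the grid must resolve the attenuation length
#' (`spacing_cm <= delta / 5`) and the boundary must be far enough that the
#' Dirichlet truncation is negligible (`domain_cm >= 10 * delta`), where
#' `delta = 1 / mu_eff` is the penetration depth.
#'
#' @param p An [optical_properties()] object (`mu_a > 0`).
#' @param domain_cm Side length of the square domain (cm).
#' @param spacing_cm Grid spacing (cm).
#' @param source_strength Total source power (relative units, default 1).
#'
#' @return A `fluence_field`: list with the `phi` matrix (nx by ny),
#'   `grid_spacing_cm`, `nx`, `ny`, `source_xy` (grid indices),
#'   `diffusion_coeff_cm`, `mu_eff_cm1`, `source_strength`.
#' @export
solve_fluence <- function(p, domain_cm, spacing_cm, source_strength = 1) {
  stopifnot(inherits(p, "optical_properties"))
  if (p$mu_a <= 0)
    stop_tl("mu_a must be > 0 for a bounded steady-state solution",
            "tl_invalid_parameter")
  Dc <- diffusion_coefficient(p)
  mu_eff <- effective_attenuation(p$mu_a, p$mu_s_prime)
  delta <- 1 / mu_eff
  if (spacing_cm > delta / 5)
    stop_tl(sprintf(
      "grid too coarse: spacing %.4g cm > delta/5 = %.4g cm (try spacing_cm <= %.4g)",
      spacing_cm, delta / 5, delta / 5), "tl_resolution_error")
  if (domain_cm < 10 * delta)
    stop_tl(sprintf(
      "domain too small: %.4g cm < 10*delta = %.4g cm (try domain_cm >= %.4g)",
      domain_cm, 10 * delta, 10 * delta), "tl_domain_error")

  h <- spacing_cm
  n <- 2 * floor(domain_cm / (2 * h)) + 1  # odd: a node sits at the centre
  ni <- n - 2                              # interior nodes per side
  idx <- function(i, j) (j - 1L) * ni + i  # interior (i, j) -> unknown index

  # five-point stencil: (mu_a + 4 D/h^2) phi_ij - (D/h^2) sum(neighbours)
  diag_val <- p$mu_a + 4 * Dc / h^2
  off_val <- -Dc / h^2
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ig <- rep(seq_len(ni), times = ni)
  jg <- rep(seq_len(ni), each = ni)
  k <- idx(ig, jg)
  add <- function(from, to, val) {
    ii <<- c(ii, from); jj <<- c(jj, to); xx <<- c(xx, rep(val, length(from)))
  }
  add(k, k, diag_val)
  left <- ig > 1;  add(k[left],  idx(ig[left] - 1L, jg[left]),  off_val)
  right <- ig < ni; add(k[right], idx(ig[right] + 1L, jg[right]), off_val)
  down <- jg > 1;  add(k[down],  idx(ig[down], jg[down] - 1L),  off_val)
  up <- jg < ni;   add(k[up],    idx(ig[up],   jg[up] + 1L),    off_val)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ni^2, ni^2))

  b <- numeric(ni^2)
  c_int <- (ni + 1L) %/% 2L            # centre in interior indexing
  b[idx(c_int, c_int)] <- source_strength / h^2  # delta of total power S
  sol <- as.numeric(Matrix::solve(A, b))

  phi <- matrix(0, n, n)
  phi[2:(n - 1), 2:(n - 1)] <- matrix(sol, ni, ni)
  structure(
    list(phi = phi, grid_spacing_cm = h, nx = n, ny = n,
         source_xy = c(c_int + 1L, c_int + 1L),
         diffusion_coeff_cm = Dc, mu_eff_cm1 = mu_eff,
         source_strength = source_strength),
    class = "fluence_field")
}

#' Analytic infinite-medium fluence profile
#'
#' The 2D steady-state Green's function
#' \eqn{\phi(r) = S K_0(\mu_{eff} r) / (2 \pi D)} used as the oracle for
#' [solve_fluence()].
#'
#' @param r_cm Radial distances (cm, > 0).
#' @param p An [optical_properties()] object.
#' @param source_strength Total source power.
#' @return Fluence rate at each radius.
#' @export
fluence_greens_2d <- function(r_cm, p, source_strength = 1) {
  Dc <- diffusion_coefficient(p)
  mu_eff <- effective_attenuation(p$mu_a, p$mu_s_prime)
  source_strength * besselK(mu_eff * r_cm, 0) / (2 * pi * Dc)
}

#' Radial half-width of a fluence field
#'
#' The radius at which the fluence falls to `fraction` of its off-source
#' maximum, measured along the grid axis through the source with linear
#' interpolation between nodes. Operationalises "more diffusive": at fixed
#' absorption the width grows as the reduced scattering coefficient drops.
#'
#' @param f A `fluence_field` from [solve_fluence()].
#' @param fraction Threshold fraction in (0, 1), default `exp(-1)`.
#' @return Width (radius) in cm.
#' @export
profile_width <- function(f, fraction = exp(-1)) {
  stopifnot(inherits(f, "fluence_field"), fraction > 0, fraction < 1)
  i0 <- f$source_xy[1]; j0 <- f$source_xy[2]
  ray <- f$phi[i0:f$nx, j0]           # axis from source to right boundary
  peak <- ray[2]                      # off-source maximum sits next to source
  if (peak <= 0)
    stop_tl("field is zero off-source", "tl_invalid_parameter")
  thr <- fraction * peak
  below <- which(ray[-1] < thr)
  if (!length(below))
    stop_tl("field never falls below the threshold inside the domain",
            "tl_domain_error")
  kb <- below[1] + 1                  # first node below threshold (>= 3)
  ka <- kb - 1
  # linear interpolation between nodes ka and kb (radii (ka-1)h, (kb-1)h)
  frac <- (ray[ka] - thr) / (ray[ka] - ray[kb])
  ((ka - 1) + frac) * f$grid_spacing_cm
}

#' Write a fluence field to disk
#'
#' Writes the grid as a CSV matrix plus a JSON sidecar holding the spacing,
#' source position and optical metadata.
#'
#' @param f A `fluence_field`.
#' @param path_csv Output CSV path; the sidecar is `path_csv` with a
#'   `.json` extension.
#' @return Invisibly, the sidecar path.
#' @export
write_fluence <- function(f, path_csv) {
  utils::write.table(f$phi, path_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- sub("\\.csv$", ".json", path_csv)
  jsonlite::write_json(
    list(grid_spacing_cm = f$grid_spacing_cm, nx = f$nx, ny = f$ny,
         source_xy = f$source_xy, diffusion_coeff_cm = f$diffusion_coeff_cm,
         mu_eff_cm1 = f$mu_eff_cm1, source_strength = f$source_strength),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
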