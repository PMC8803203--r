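#' Ground-truth optical-property trend for a tissue fixture
#'
#' Returns the per-power ground truth the synthetic-data generator uses:
#' the reduced scattering coefficient falls linearly with incident power
#' between published endpoints (skull: 37 to 9 1/cm; skin: 12 to 5.8 1/cm
#' over 150 to 350 mW), the absorption coefficient is constant across
#' powers, and the anisotropy factor rises linearly from 0.80 to 0.90.
#'
#' The absorption (0.5 and 0.8 1/cm) and thickness (0.1 and 0.2 cm)
#' fixtures are synthetic package choices of realistic magnitude, not
#' measured values; only the mu_s' endpoints are literature-anchored.
#'
#' @param tissue `"skull"` or `"skin"`.
#' @param powers_mw Incident powers in mW (default the six-power series
#'   150, 200, 225, 250, 300, 350).
#'
#' @return A data frame of class `ground_truth_trend` with columns
#'   `tissue`, `power_mw`, `mu_s_prime_cm1`, `mu_a_cm1`, `thickness_cm`, `g`.
#' @export
#' @examples
#' default_ground_truth("skull")
default_ground_truth <- function(tissue = c("skull", "skin"),
                                 powers_mw = c(150, 200, 225, 250, 300, 350)) {
  tissue <- match.arg(tissue)
  ends <- switch(tissue,
    skull = list(msp = c(37, 9),  mua = 0.5, thick = 0.1),
    skin  = list(msp = c(12, 5.8), mua = 0.8, thick = 0.2))
  frac <- (powers_mw - 150) / (350 - 150)
  out <- data.frame(
    tissue = tissue,
    power_mw = powers_mw,
    mu_s_prime_cm1 = ends$msp[1] + (ends$msp[2] - ends$msp[1]) * frac,
    mu_a_cm1 = ends$mua,
    thickness_cm = ends$thick,
    g = 0.80 + (0.90 - 0.80) * frac)
  class(out) <- c("ground_truth_trend", class(out))
  out
}

# CV -> lognormal(meanlog, sdlog) with unit mean
lnorm_pars <- function(cv) {
  s2 <- log(1 + cv^2)
  list(meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a table of noisy diffuse fractions from a ground-truth trend
#'
#' For each power the noise-free `(r_d, t_d)` pair is the forward two-flux
#' prediction of the ground-truth transport coefficients
#' (`forward_km(transport_to_km(...))`). Each replicate multiplies `r_d`
#' and `t_d` by independent lognormal factors with unit mean and
#' coefficient of variation `noise_cv` (intensities are positive and
#' detector noise is roughly proportional at these signal levels), then
#' rescales the rare draws with `r_d + t_d >= 1` back to physical range.
#'
#' @param truth A `ground_truth_trend` from [default_ground_truth()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param n_replicates Replicates per power (>= 1; the measurement protocol
#'   uses 5).
#' @param seed Integer seed; same seed gives an identical table.
#'
#' @return Data frame with columns `power_mw`, `replicate_id`, `r_d`, `t_d`,
#'   `thickness_cm`, plus attribute `seed`.
#' @export
#' @examples
#' rt <- make_rt_table(default_ground_truth("skull"), noise_cv = 0, n_replicates = 1, seed = 1)
make_rt_table <- function(truth, noise_cv = 0.05, n_replicates = 5, seed = 42) {
  stopifnot(inherits(truth, "ground_truth_trend"),
            noise_cv >= 0, n_replicates >= 1)
  clean <- lapply(seq_len(nrow(truth)), function(i) {
    p <- optical_properties(mu_a = truth$mu_a_cm1[i],
                            mu_s_prime = truth$mu_s_prime_cm1[i],
                            thickness_cm = truth$thickness_cm[i])
    forward_km_props(p)
  })
  lp <- lnorm_pars(noise_cv)
  out <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      for (rep in seq_len(n_replicates)) {
        fac <- if (noise_cv > 0) rlnorm(2, lp$meanlog, lp$sdlog) else c(1, 1)
        r <- clean[[i]]$r_d * fac[1]
        t <- clean[[i]]$t_d * fac[2]
        tot <- r + t
        if (tot >= 1) {  # clip back inside the physical simplex
          scl <- (1 - 1e-6) / tot
          r <- r * scl; t <- t * scl
        }
        rows[[length(rows) + 1]] <- data.frame(
          power_mw = truth$power_mw[i], replicate_id = rep,
          r_d = r, t_d = t, thickness_cm = truth$thickness_cm[i])
      }
    }
    do.call(rbind, rows)
  })
  attr(out, "seed") <- seed
  out
}

# forward model straight from transport properties
forward_km_props <- function(p) {
  k <- transport_to_km(p)
  forward_km(k$s_km, k$a_km, p$thickness_cm)
}

#' Write synthetic integrating-sphere spectra and a manifest
#'
#' Emulates the raw spectrometer traces behind [make_rt_table()]: every
#' trace is a Gaussian diode-laser line centred at 808 nm (FWHM 3 nm) on a
#' 750-860 nm grid. The empty-sphere reference transmission carries the
#' full line, the reference reflection is dark, and each sample trace is
#' the reference line scaled by that replicate's noisy `r_d` or `t_d`, so
#' that band-integration plus empty-sphere calibration reproduces the
#' [make_rt_table()] fractions essentially exactly.
#'
#' @inheritParams make_rt_table
#' @param outdir Output directory (created if missing).
#' @param fwhm_nm Laser-line full width at half maximum (nm).
#' @param grid_nm Wavelength grid step (nm).
#'
#' @return Invisibly, the manifest data frame. Side effects: one CSV per
#'   trace, `manifest.csv`, and `ground_truth.csv` (the recovery-test key)
#'   in `outdir`.
#' @export
make_spectra <- function(truth, noise_cv = 0.05, n_replicates = 5, seed = 42,
                         outdir, fwhm_nm = 3, grid_nm = 0.5) {
  rt <- make_rt_table(truth, noise_cv, n_replicates, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    stop_tl(sprintf("cannot create output directory %s", outdir), "tl_io_error")
  wl <- seq(750, 860, by = grid_nm)
  sg <- fwhm_nm / (2 * sqrt(2 * log(2)))
  line <- exp(-(wl - 808)^2 / (2 * sg^2))

  write_trace <- function(fname, intensity) {
    con <- file.path(outdir, fname)
    writeLines(c("# wavelength_nm,intensity",
                 sprintf("%.6g,%.10g", wl, intensity)), con)
    fname
  }
  man <- list()
  add <- function(path, mode, power, rep) {
    man[[length(man) + 1]] <<- data.frame(
      path = path, mode = mode, power_mw = power, replicate_id = rep,
      sample_id = truth$tissue[1])
  }
  for (p in unique(rt$power_mw)) {
    amp <- 1000 * p / 150  # counts scale with incident power
    add(write_trace(sprintf("ref_T_%g.csv", p), amp * line),
        "reference_transmission", p, 1L)
    add(write_trace(sprintf("ref_R_%g.csv", p), 0 * line),
        "reference_reflection", p, 1L)
    sub <- rt[rt$power_mw == p, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub$replicate_id[i]
      add(write_trace(sprintf("sam_T_%g_r%d.csv", p, r),
                      amp * sub$t_d[i] * line), "transmission", p, r)
      add(write_trace(sprintf("sam_R_%g_r%d.csv", p, r),
                      amp * sub$r_d[i] * line), "reflection", p, r)
    }
  }
  man <- do.call(rbind, man)
  man$seed <- seed
  write.csv(man, file.path(outdir, "manifest.csv"), row.names = FALSE)
  write.csv(as.data.frame(truth), file.path(outdir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(man)
}
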