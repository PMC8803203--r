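#' Read a spectrometer trace
#'
#' Parses a two-column delimited text file (wavelength in nm, intensity in
#' counts) into a `spectrum_record`. Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param mode One of `"transmission"`, `"reflection"`,
#'   `"reference_transmission"`, `"reference_reflection"`.
#' @param power_mw Incident power in mW.
#' @param replicate_id Replicate index (integer >= 1).
#' @param sample_id Sample label.
#' @param sep Field separator (default `","`).
#'
#' @return A `spectrum_record`: list with `wavelength_nm`, `intensity`,
#'   `mode`, `power_mw`, `replicate_id`, `sample_id`.
#' @export
read_spectrum <- function(path, mode, power_mw = NA_real_, replicate_id = 1L,
                          sample_id = "sample", sep = ",") {
  mode <- match.arg(mode, c("transmission", "reflection",
                            "reference_transmission", "reference_reflection"))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    stop_tl(sprintf("empty spectrum file: %s", path), "tl_parse_error")
  rows <- which(keep)
  parsed <- strsplit(trimws(lines[keep]), sep, fixed = TRUE)
  bad <- which(vapply(parsed, length, 1L) != 2L)
  if (length(bad))
    stop_tl(sprintf("malformed rows (expected 2 fields) at line(s) %s in %s",
                    paste(rows[bad], collapse = ", "), path), "tl_parse_error")
  wl <- suppressWarnings(as.numeric(vapply(parsed, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parsed, `[`, "", 2L)))
  bad <- which(!is.finite(wl) | !is.finite(it))
  if (length(bad))
    stop_tl(sprintf("non-numeric values at line(s) %s in %s",
                    paste(rows[bad], collapse = ", "), path), "tl_parse_error")
  spectrum_record(wl, it, mode = mode, power_mw = power_mw,
                  replicate_id = replicate_id, sample_id = sample_id)
}

#' Construct a spectrum record
#'
#' @param wavelength_nm Strictly ascending wavelength grid (nm), length >= 2.
#' @param intensity Non-negative counts, same length.
#' @inheritParams read_spectrum
#' @return A `spectrum_record`.
#' @export
spectrum_record <- function(wavelength_nm, intensity, mode = "transmission",
                            power_mw = NA_real_, replicate_id = 1L,
                            sample_id = "sample") {
  if (length(wavelength_nm) < 2 || length(wavelength_nm) != length(intensity))
    stop_tl("wavelength and intensity must be equal length >= 2",
            "tl_parse_error")
  if (any(diff(wavelength_nm) <= 0))
    stop_tl("wavelengths must be strictly ascending", "tl_parse_error")
  if (any(intensity < 0))
    stop_tl("negative intensity counts", "tl_parse_error")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity),
                 mode = mode, power_mw = power_mw,
                 replicate_id = as.integer(replicate_id),
                 sample_id = sample_id),
            class = "spectrum_record")
}

#' Integrate a spectrum over a wavelength band
#'
#' Trapezoidal integral of the intensity over
#' `[center_nm - halfwidth_nm, center_nm + halfwidth_nm]`, with linear
#' interpolation at the band edges so partial grid cells contribute their
#' exact trapezoid. Reduces a full trace to a single band intensity at the
#' laser line (808 nm by default elsewhere).
#'
#' @param s A `spectrum_record`.
#' @param center_nm Band centre (nm).
#' @param halfwidth_nm Band half width (nm, > 0).
#' @return Integrated counts-nm (non-negative scalar).
#' @export
band_integral <- function(s, center_nm, halfwidth_nm) {
  stopifnot(inherits(s, "spectrum_record"), halfwidth_nm > 0)
  lo <- center_nm - halfwidth_nm
  hi <- center_nm + halfwidth_nm
  wl <- s$wavelength_nm; it <- s$intensity
  if (hi < wl[1] || lo > wl[length(wl)])
    stop_tl(sprintf("band [%g, %g] nm does not overlap trace range [%g, %g] nm",
                    lo, hi, wl[1], wl[length(wl)]), "tl_out_of_range")
  lo <- max(lo, wl[1]); hi <- min(hi, wl[length(wl)])
  inside <- wl > lo & wl < hi
  xs <- c(lo, wl[inside], hi)
  ys <- c(approx(wl, it, lo)$y, it[inside], approx(wl, it, hi)$y)
  sum(diff(xs) * (head2(ys) + tail2(ys)) / 2)
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' Calibrate diffuse fractions against the empty-sphere reference
#'
#' Converts band intensities of the four integrating-sphere traces into
#' diffuse fractions. In an empty sphere the incident beam is recorded
#' entirely as transmittance and there is (almost) no reflected intensity,
#' so the empty-sphere transmission band serves as the 100% level:
#' `t_d = band(sample_T) / band(ref_T)` and
#' `r_d = (band(sample_R) - band(ref_R)) / band(ref_T)` (clipped at 0).
#'
#' @param sample_T,sample_R Sample-in-place transmission and reflection
#'   traces (`spectrum_record`) or pre-computed band intensities (numeric).
#' @param ref_T,ref_R Empty-sphere reference traces or band intensities.
#' @param center_nm,halfwidth_nm Band passed to [band_integral()] when
#'   traces are given. Defaults 808 and 5 nm.
#'
#' @return A list with `r_d` and `t_d`. A result with `r_d + t_d >= 1` is
#'   returned as-is with a warning (flagged, not silently repaired): the
#'   downstream inversion rejects it.
#' @export
calibrate_fractions <- function(sample_T, sample_R, ref_T, ref_R,
                                center_nm = 808, halfwidth_nm = 5) {
  bi <- function(x) {
    if (inherits(x, "spectrum_record")) band_integral(x, center_nm, halfwidth_nm)
    else as.numeric(x)
  }
  bT <- bi(sample_T); bR <- bi(sample_R)
  rT <- bi(ref_T);    rR <- bi(ref_R)
  if (!is.finite(rT) || rT <= 0)
    stop_tl("reference transmission band is <= 0: cannot calibrate",
            "tl_calibration_error")
  t_d <- bT / rT
  r_d <- max(0, (bR - rR) / rT)
  if (r_d + t_d > 1 + 1e-9)  # the empty-sphere identity sits exactly at 1
    warning(sprintf("non-physical calibrated fractions: r_d + t_d = %.4f >= 1",
                    r_d + t_d))
  list(r_d = r_d, t_d = t_d)
}

#' Replicate mean and rms deviation
#'
#' Summarises repeated measurements of the same quantity by their arithmetic
#' mean and the root-mean-square deviation about the mean (population form,
#' divisor `n`). Set `deviation = FALSE` for the rms of the raw values
#' instead.
#'
#' @param values Numeric vector over replicates (length >= 1).
#' @param deviation If `TRUE` (default) rms is taken about the mean.
#' @return A list with `mean_value`, `rms_value`, `n_replicates`.
#' @export
#' @examples
#' replicate_stats(c(1, 3))  # mean 2, rms 1
replicate_stats <- function(values, deviation = TRUE) {
  if (length(values) == 0 || !all(is.finite(values)))
    stop_tl("values must be a non-empty finite numeric vector",
            "tl_invalid_parameter")
  m <- mean(values)
  rms <- if (deviation) sqrt(mean((values - m)^2)) else sqrt(mean(values^2))
  list(mean_value = m, rms_value = rms, n_replicates = length(values))
}

#' Reduce a manifest of spectrum files to a diffuse-fraction table
#'
#' Reads every trace listed in a manifest (columns `path`, `mode`,
#' `power_mw`, `replicate_id`, `sample_id`), band-integrates each at the
#' laser line, and calibrates sample bands against the empty-sphere
#' reference of the same power, producing one `(r_d, t_d)` row per
#' (power, replicate).
#'
#' @param manifest_path Path to the manifest CSV. Relative `path` entries
#'   are resolved against the manifest's directory.
#' @param center_nm,halfwidth_nm Integration band (defaults 808, 5 nm).
#' @param thickness_cm Optional slab thickness recorded into the output.
#'
#' @return Data frame with columns `power_mw`, `replicate_id`, `r_d`, `t_d`
#'   (and `thickness_cm` when given), ordered by power then replicate.
#' @export
reduce_manifest <- function(manifest_path, center_nm = 808, halfwidth_nm = 5,
                            thickness_cm = NULL) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("path", "mode", "power_mw", "replicate_id")
  if (!all(need %in% names(man)))
    stop_tl(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
            "tl_parse_error")
  base <- dirname(manifest_path)
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(base, man$path))
  band <- vapply(seq_len(nrow(man)), function(i) {
    s <- read_spectrum(man$path[i], mode = man$mode[i],
                       power_mw = man$power_mw[i],
                       replicate_id = man$replicate_id[i])
    band_integral(s, center_nm, halfwidth_nm)
  }, 0.0)
  man$band <- band

  rows <- list()
  for (p in sort(unique(man$power_mw))) {
    sub <- man[man$power_mw == p, ]
    refT <- sub$band[sub$mode == "reference_transmission"]
    refR <- sub$band[sub$mode == "reference_reflection"]
    if (!length(refT))
      stop_tl(sprintf("no reference_transmission trace for power %g mW", p),
              "tl_calibration_error")
    refT <- mean(refT)
    refR <- if (length(refR)) mean(refR) else 0
    reps <- sort(unique(sub$replicate_id[sub$mode %in%
                                           c("transmission", "reflection")]))
    for (r in reps) {
      bT <- sub$band[sub$mode == "transmission" & sub$replicate_id == r]
      bR <- sub$band[sub$mode == "reflection" & sub$replicate_id == r]
      if (length(bT) != 1 || length(bR) != 1)
        stop_tl(sprintf(
          "power %g mW replicate %d: need exactly one transmission and one reflection trace",
          p, r), "tl_calibration_error")
      fr <- calibrate_fractions(bT, bR, refT, refR)
      rows[[length(rows) + 1]] <- data.frame(
        power_mw = p, replicate_id = r, r_d = fr$r_d, t_d = fr$t_d)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(thickness_cm)) out$thickness_cm <- thickness_cm
  out
}
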