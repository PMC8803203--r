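write_trace <- function(rows, ...) {
  path <- withr::local_tempfile(fileext = ".csv", ...)
  writeLines(rows, path)
  path
}

test_that("read_spectrum parses well-formed files and reports bad ones", {
  p <- write_trace(c("# laser line", "800,10", "808,500", "816,12"),
                   .local_envir = parent.frame())
  s <- read_spectrum(p, mode = "transmission", power_mw = 150)
  expect_s3_class(s, "spectrum_record")
  expect_length(s$wavelength_nm, 3)
  expect_equal(s$intensity[2], 500)

  bad <- write_trace(c("808,5", "800,6"), .local_envir = parent.frame())
  expect_error(read_spectrum(bad, "transmission"), class = "tl_parse_error")

  neg <- write_trace(c("800,5", "808,-1"), .local_envir = parent.frame())
  expect_error(read_spectrum(neg, "transmission"), class = "tl_parse_error")

  empty <- write_trace("# nothing", .local_envir = parent.frame())
  expect_error(read_spectrum(empty, "transmission"), class = "tl_parse_error")

  malformed <- write_trace(c("800,5", "808"), .local_envir = parent.frame())
  err <- tryCatch(read_spectrum(malformed, "transmission"),
                  error = conditionMessage)
  expect_match(err, "line\\(s\\) 2")  # offending line is named
})

test_that("band_integral is an exact trapezoid with edge interpolation", {
  # constant intensity c over a fully covered band of width w gives c*w
  s <- spectrum_record(seq(750, 860, 1), rep(7, 111))
  expect_equal(band_integral(s, 808, 5), 7 * 10, tolerance = 1e-12)
  # band edges between grid nodes still integrate exactly for a constant
  expect_equal(band_integral(s, 808, 4.3), 7 * 8.6, tolerance = 1e-12)

  # zero intensity integrates to zero
  s0 <- spectrum_record(seq(750, 860, 1), rep(0, 111))
  expect_equal(band_integral(s0, 808, 5), 0)

  # triangular peak height h, base 2w fully inside the band: area h*w
  wl <- seq(750, 860, 0.01)
  h <- 100; w <- 3
  tri <- pmax(0, h * (1 - abs(wl - 808) / w))
  st <- spectrum_record(wl, tri)
  expect_equal(band_integral(st, 808, 5), h * w, tolerance = 1e-4)

  # additivity over adjacent disjoint bands
  st2 <- spectrum_record(wl, tri + 1)
  expect_equal(band_integral(st2, 805.5, 2.5) + band_integral(st2, 810.5, 2.5),
               band_integral(st2, 808, 5), tolerance = 1e-9)

  expect_error(band_integral(s, 900, 5), class = "tl_out_of_range")
})

test_that("calibrate_fractions implements the empty-sphere normalisation", {
  wl <- seq(750, 860, 0.5)
  line <- 1000 * exp(-(wl - 808)^2 / 2)
  refT <- spectrum_record(wl, line, mode = "reference_transmission")
  refR <- spectrum_record(wl, 0 * line, mode = "reference_reflection")

  # empty-sphere identity: sample == reference
  fr <- calibrate_fractions(refT, refR, refT, refR)
  expect_equal(fr$r_d, 0)
  expect_equal(fr$t_d, 1, tolerance = 1e-12)

  # linear scaling: T halves, R gains 0.3 of the reference line
  samT <- spectrum_record(wl, 0.5 * line)
  samR <- spectrum_record(wl, 0.3 * line)
  fr <- calibrate_fractions(samT, samR, refT, refR)
  expect_equal(fr$t_d, 0.5, tolerance = 1e-12)
  expect_equal(fr$r_d, 0.3, tolerance = 1e-12)

  # scale invariance: common gain cancels
  gain <- 17.3
  fr2 <- calibrate_fractions(
    spectrum_record(wl, gain * 0.5 * line),
    spectrum_record(wl, gain * 0.3 * line),
    spectrum_record(wl, gain * line),
    spectrum_record(wl, gain * 0 * line))
  expect_equal(fr2$t_d, fr$t_d, tolerance = 1e-12)
  expect_equal(fr2$r_d, fr$r_d, tolerance = 1e-12)

  expect_error(calibrate_fractions(samT, samR, refR, refR),
               class = "tl_calibration_error")
  expect_warning(calibrate_fractions(0.8, 0.5, 1, 0), "non-physical")
})

test_that("replicate_stats computes mean and population rms deviation", {
  st <- replicate_stats(c(5, 5, 5, 5, 5))
  expect_equal(st$mean_value, 5)
  expect_equal(st$rms_value, 0)

  st <- replicate_stats(c(1, 3))
  expect_equal(st$mean_value, 2)
  expect_equal(st$rms_value, 1)

  # frozen hand computation for a five-replicate protocol
  st <- replicate_stats(c(0.46, 0.44, 0.47, 0.45, 0.43))
  expect_equal(st$mean_value, 0.45)
  expect_equal(st$rms_value, 0.01414214, tolerance = 1e-6)
  expect_equal(st$n_replicates, 5)

  # translation invariance and linear scaling of the rms
  v <- c(0.2, 0.5, 0.9, 1.1)
  expect_equal(replicate_stats(v + 10)$rms_value,
               replicate_stats(v)$rms_value, tolerance = 1e-12)
  expect_equal(replicate_stats(3 * v)$rms_value,
               3 * replicate_stats(v)$rms_value, tolerance = 1e-12)

  # raw-rms option
  expect_equal(replicate_stats(c(3, 4), deviation = FALSE)$rms_value,
               sqrt(12.5))
  expect_error(replicate_stats(numeric(0)), class = "tl_invalid_parameter")
})

test_that("reduce_manifest turns a spectra directory into an R/T table", {
  outdir <- withr::local_tempdir()
  truth <- skull_truth()
  make_spectra(truth, noise_cv = 0, n_replicates = 2, seed = 1,
               outdir = outdir)
  tab <- reduce_manifest(file.path(outdir, "manifest.csv"),
                         thickness_cm = truth$thickness_cm[1])
  expect_equal(nrow(tab), 6 * 2)
  expect_setequal(unique(tab$power_mw), truth$power_mw)
  # noise-free reduction must agree with the direct forward model
  rt_direct <- make_rt_table(truth, noise_cv = 0, n_replicates = 1, seed = 1)
  for (p in truth$power_mw) {
    expect_equal(tab$t_d[tab$power_mw == p][1],
                 rt_direct$t_d[rt_direct$power_mw == p], tolerance = 1e-3)
    expect_equal(tab$r_d[tab$power_mw == p][1],
                 rt_direct$r_d[rt_direct$power_mw == p], tolerance = 1e-3)
  }
})
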