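test_that("forward_km matches its closed-form limits and frozen oracle values", {
  # zero-absorption limit: R = SD/(1+SD), T = 1/(1+SD); SD = 1 here
  rt <- forward_km(s_km = 10, a_km = 0, thickness_cm = 0.1)
  expect_equal(rt$r_d, 0.5)
  expect_equal(rt$t_d, 0.5)

  # frozen high-precision evaluation of the consistent form, X = 1.1
  rt <- forward_km(10, 1, 0.1)
  expect_equal(rt$r_d, 0.4610336233, tolerance = 1e-9)
  expect_equal(rt$t_d, 0.4452842133, tolerance = 1e-9)
  # X recovered from the output must equal 1 + a/s (the identity that
  # pins down the correct forward form)
  x <- (1 + rt$r_d^2 - rt$t_d^2) / (2 * rt$r_d)
  expect_equal(x, 1.1, tolerance = 1e-9)

  # vanishing slab transmits everything
  rt <- forward_km(10, 1, 1e-9)
  expect_lt(rt$r_d, 1e-7)
  expect_gt(rt$t_d, 1 - 1e-7)

  # optically thick asymptote: r_d -> 1/(X+Y), t_d -> 0, no overflow
  rt <- forward_km(50, 5, 1000)
  expect_equal(rt$r_d, 1 / (1.1 + sqrt(1.1^2 - 1)), tolerance = 1e-9)
  expect_equal(rt$t_d, 0)

  expect_error(forward_km(-1, 0, 0.1), class = "tl_invalid_parameter")
  expect_error(forward_km(10, 0, 0), class = "tl_invalid_parameter")
})

test_that("invert_km recovers coefficients and rejects non-physical input", {
  k <- invert_km(diffuse_measurement(0.5, 0.5, 0.1))
  expect_equal(k$s_km, 10, tolerance = 1e-9)
  expect_equal(k$a_km, 0)

  k <- invert_km(diffuse_measurement(0.4610336233, 0.4452842133, 0.1))
  expect_equal(k$s_km, 10, tolerance = 1e-6)
  expect_equal(k$a_km, 1, tolerance = 1e-6)
  expect_equal(k$x, 1.1, tolerance = 1e-7)
  expect_equal(k$y, sqrt(k$x^2 - 1), tolerance = 1e-12)

  # forward of the inverse reproduces the measurement
  rt <- forward_km(k$s_km, k$a_km, 0.1)
  expect_equal(rt$r_d, 0.4610336233, tolerance = 1e-9)
  expect_equal(rt$t_d, 0.4452842133, tolerance = 1e-9)

  expect_error(diffuse_measurement(0.6, 0.5, 0.1),
               class = "tl_nonphysical_measurement")
  expect_error(diffuse_measurement(0, 0.5, 0.1),
               class = "tl_invalid_parameter")
})

test_that("round-trip identity holds on the full parameter grid", {
  grid <- expand.grid(s = c(0.5, 1, 5, 10, 30, 50),
                      a = c(0, 0.1, 1, 5),
                      d = c(0.01, 0.1, 0.3))
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]; a <- grid$a[i]; d <- grid$d[i]
    rt <- forward_km(s, a, d)
    # energy: absorbed fraction non-negative, zero iff a = 0
    absorbed <- 1 - rt$r_d - rt$t_d
    if (a == 0) expect_equal(absorbed, 0, tolerance = 1e-12)
    else expect_gt(absorbed, 0)
    k <- invert_km(diffuse_measurement(rt$r_d, rt$t_d, d))
    expect_equal(k$s_km, s, tolerance = 1e-6)
    expect_equal(k$a_km, a, tolerance = 1e-6 * max(1, a))
    # Eq-3 consistency of the auxiliary parameter
    expect_equal(k$x, 1 + a / s, tolerance = 1e-9)
  }
})

test_that("forward_km is monotone in its coefficients", {
  s_grid <- c(1, 2, 5, 10, 20, 50)
  r <- vapply(s_grid, function(s) forward_km(s, 0.5, 0.1)$r_d, 0)
  expect_true(all(diff(r) > 0))  # r_d increases with s_km
  a_grid <- c(0, 0.5, 1, 2, 5)
  t <- vapply(a_grid, function(a) forward_km(10, a, 0.1)$t_d, 0)
  expect_true(all(diff(t) < 0))  # t_d decreases with a_km
})

test_that("transport conversion matches the two-flux correspondence both ways", {
  p <- km_to_transport(km_coefficients(10, 1), thickness_cm = 0.1)
  expect_equal(p$mu_a, 0.5)
  expect_equal(p$mu_s_prime, 13.5)

  k <- transport_to_km(optical_properties(0.5, 13.5, 0.1))
  expect_equal(k$s_km, 10)
  expect_equal(k$a_km, 1)

  # zero absorption: s_km = 0.75 mu_s', mu_s' = 4 s/3
  p0 <- km_to_transport(km_coefficients(9, 0), thickness_cm = 0.1)
  expect_equal(p0$mu_a, 0)
  expect_equal(p0$mu_s_prime, 12)

  # round trip is an algebraic identity
  for (pars in list(c(0.2, 5), c(2, 30), c(0.01, 0.1))) {
    k2 <- transport_to_km(optical_properties(pars[1], pars[2], 0.1))
    p2 <- km_to_transport(k2, 0.1)
    expect_equal(p2$mu_a, pars[1], tolerance = 1e-12)
    expect_equal(p2$mu_s_prime, pars[2], tolerance = 1e-12)
  }

  # scattering-dominance guard
  expect_error(transport_to_km(optical_properties(3, 1, 0.1)),
               class = "tl_km_inapplicable")
})

test_that("penetration depth follows 1/mu_eff with the documented limits", {
  p <- optical_properties(0.5, 13.5, 0.1)
  expect_equal(penetration_depth(p), 1 / sqrt(21), tolerance = 1e-12)
  # closed-form limit mu_s' = 0
  expect_equal(penetration_depth(optical_properties(2, 0, 0.1)),
               1 / (2 * sqrt(3)), tolerance = 1e-12)
  # depth grows when scattering drops at fixed absorption
  expect_gt(penetration_depth(optical_properties(0.5, 9, 0.1)),
            penetration_depth(optical_properties(0.5, 37, 0.1)))
  # shared definition with the fluence solver
  f <- solve_fluence(p, domain_cm = 3, spacing_cm = 0.04)
  expect_equal(f$mu_eff_cm1 * penetration_depth(p), 1, tolerance = 1e-12)
  expect_warning(d <- penetration_depth(optical_properties(0, 10, 0.1)),
                 "infinite")
  expect_identical(d, Inf)
})

test_that("estimate_optical_properties composes inversion and conversion", {
  p <- estimate_optical_properties(
    diffuse_measurement(0.4610336233, 0.4452842133, 0.1, power_mw = 250))
  expect_equal(p$mu_a, 0.5, tolerance = 1e-6)
  expect_equal(p$mu_s_prime, 13.5, tolerance = 1e-6)
  expect_equal(p$power_mw, 250)      # metadata carried through
  expect_equal(p$thickness_cm, 0.1)

  # zero-absorption branch then conversion
  p0 <- estimate_optical_properties(diffuse_measurement(0.5, 0.5, 0.1))
  expect_equal(p0$mu_a, 0)
  expect_equal(p0$mu_s_prime, 40 / 3, tolerance = 1e-9)

  # full round trip from arbitrary transport values
  truth <- optical_properties(0.7, 22, 0.15)
  rt <- forward_km(transport_to_km(truth)$s_km, transport_to_km(truth)$a_km,
                   0.15)
  rec <- estimate_optical_properties(
    diffuse_measurement(rt$r_d, rt$t_d, 0.15))
  expect_equal(rec$mu_a, 0.7, tolerance = 1e-6)
  expect_equal(rec$mu_s_prime, 22, tolerance = 1e-6)
})

test_that("invert_rt_table vectorises the chain with the expected columns", {
  rt <- forward_km(10, 1, 0.1)
  tab <- data.frame(power_mw = c(150, 350), r_d = rt$r_d, t_d = rt$t_d,
                    thickness_cm = 0.1, replicate_id = 1:2)
  out <- invert_rt_table(tab)
  expect_named(out, c("power_mw", "mu_a_cm1", "mu_s_prime_cm1", "s_km_cm1",
                      "a_km_cm1", "penetration_depth_cm", "replicate_id"))
  expect_equal(out$mu_a_cm1, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(out$penetration_depth_cm, rep(1 / sqrt(21), 2),
               tolerance = 1e-6)
  expect_error(invert_rt_table(tab[, 1:3]), class = "tl_invalid_parameter")
})
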