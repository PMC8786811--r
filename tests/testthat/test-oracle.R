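# Reference values below were computed with an independent numerical
# oracle (adaptive QUADPACK integration of the kink-free region
# decomposition, cross-checked by inclusion-exclusion of spherical caps
# and by >= 5e7-sample rejection Monte Carlo); they are frozen here.

test_that("N = 1 closed form: plateau, linear decay, endpoints", {
  expect_equal(w_exact_n1(c(0, 0.5, 1), 0.5, 1), c(1, 1, 1))
  expect_equal(w_exact_n1(4, 0, 1), 0)
  expect_equal(w_exact_n1(1, 0, 1), 0.5)
  cs <- seq(0, 4.5, by = 0.01)
  w <- w_exact_n1(cs, 0.3, 1)
  expect_true(all(diff(w) <= 1e-14))
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w_exact_n1(4 * 0.3^2 + 1e-12, 0.3, 1), 1, tolerance = 1e-9)
})

test_that("quadrature oracle matches independent reference values (N = 2)", {
  expect_equal(w_quadrature(0.5, sys_n2_l0), 0.4429576991783664,
               tolerance = 1e-10)
  expect_equal(w_quadrature(1.0, sys_n2_l0), 0.2588386269347891,
               tolerance = 1e-10)
  expect_equal(w_quadrature(1.5, sys_n2_l08), 0.8901555572221256,
               tolerance = 1e-10)
  expect_equal(w_quadrature(3.0, sys_n2_l0), 0.0025786104526242,
               tolerance = 1e-10)
  expect_equal(w_quadrature(3.9, sys_n2_l08), 4.3053034060789e-05,
               tolerance = 1e-10)
  # c = c2/2 sits on the branch boundary where the integrand has a corner
  # kink; convergence there is algebraic rather than spectral
  expect_equal(w_quadrature(2.0, sys_n2_l08), 0.4576056010,
               tolerance = 2e-6)
})

test_that("quadrature oracle agrees with high-count Monte Carlo (N = 3)", {
  # frozen independent MC: 2e8 draws (SE 2.4e-5) and 5e7 draws (SE 5.7e-5)
  expect_equal(w_quadrature(1.0, sys_n3_l0), 0.126778,
               tolerance = 3 * 2.4e-5 / 0.1268)
  expect_equal(w_quadrature(2.0, sys_n3_l08), 0.208142,
               tolerance = 3 * 5.7e-5 / 0.208)
})

test_that("oracle properties: plateau, saturation zero, monotonicity, scaling", {
  th2 <- thresholds(sys_n2_l08)
  expect_equal(w_quadrature(th2[["c1"]] * 0.9, sys_n2_l08), 1)
  expect_equal(w_quadrature(th2[["c2"]] + 0.1, sys_n2_l08), 0)
  expect_equal(w_quadrature(thresholds(sys_n3_l08)[["c1"]] * 0.5,
                            sys_n3_l08), 1)
  for (sys in list(sys_n2_l0, sys_n2_l08)) {
    cs <- seq(0.05, 3.99, length.out = 60)
    w <- w_quad_vec(cs, sys)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
  }
  # scaling invariance, exact
  for (cval in c(0.6, 1.7, 3.2)) {
    expect_equal(w_quadrature(cval, sys_n2_l08),
                 w_quadrature(cval / 9, system_spec(2, 0.8 / 3, 1 / 3)),
                 tolerance = 1e-12)
    expect_equal(w_quadrature(cval, sys_n3_l0),
                 w_quadrature(cval * 4, system_spec(3, 0, 2)),
                 tolerance = 1e-12)
  }
})

test_that("quadrature is stable under order doubling", {
  for (cval in c(0.7, 1.6, 3.3, 3.995)) {
    expect_equal(w_quadrature(cval, sys_n2_l08, n_y = 64),
                 w_quadrature(cval, sys_n2_l08, n_y = 128),
                 tolerance = 1e-9)
  }
  # N = 3 saturation: tiny smooth corner region, spectral convergence
  expect_equal(w_quadrature(3.9995, sys_n3_l0, n_y = 12, n_t = 16),
               w_quadrature(3.9995, sys_n3_l0, n_y = 24, n_t = 32),
               tolerance = 1e-8)
  # N = 3 mid-range: kink surfaces limit convergence to ~1e-5 relative
  expect_equal(w_quadrature(1.0, sys_n3_l0, n_y = 16, n_t = 24),
               w_quadrature(1.0, sys_n3_l0, n_y = 24, n_t = 32),
               tolerance = 1e-4)
})

test_that("brute-force shell sampling matches the quadrature everywhere W > 1e-3", {
  cs <- seq(0.4, 3.6, length.out = 9)
  sh <- sample_shell(sys_n2_l08, cs, n_per_point = 2e5, seed = 101)
  truth <- w_quad_vec(cs, sys_n2_l08)
  keep <- truth > 1e-3
  expect_true(all(abs(sh$W - truth)[keep] <=
                    3 * pmax(sh$SE[keep], 1e-6)))
})

test_that("gamma estimation calibrates at N = 1 and is lambda-independent", {
  g1 <- estimate_gammas(1)
  expect_equal(g1$gamma_N, 1 / 8, tolerance = 1e-6)
  expect_equal(g1$gamma_check_N, 1 / 4, tolerance = 1e-6)
  g2a <- estimate_gammas(2, system_spec(2, 0.8, 1))
  g2b <- estimate_gammas(2, system_spec(2, 0.5, 1))
  expect_equal(g2a$gamma_N, g2b$gamma_N, tolerance = 1e-3)
  expect_equal(g2a$gamma_check_N, g2b$gamma_check_N, tolerance = 1e-3)
  # positivity of the induced limit-law prefactors
  tp <- theoretical_prefactors(sys_n2_l08, g2a)
  expect_true(tp$a > 0 && tp$b > 0)
  # a too-shallow window (far from the limit) trips the curvature guard
  expect_error(estimate_gammas(2, system_spec(2, 0.8, 1), window = 1.5),
               "curvature")
})

test_that("synthetic curves are reproducible and respect the endpoints", {
  spec <- synthetic_curve_spec("interp_params",
                               interp_params(2, 1.5, 2.2, 1.9, 1.8),
                               noise_sd = 1e-3, n_points = 51, seed = 42)
  a <- synth_curve(spec); b <- synth_curve(spec)
  expect_identical(a$W, b$W)
  expect_equal(a$W[a$u == 0], 1)
  expect_equal(a$W[a$u == 1], 0)
  expect_true(all(a$W >= 0 & a$W <= 1))
  spec2 <- synthetic_curve_spec("power_law",
                                list(regime = "onset", a = 0.5, alpha = 1.5),
                                n_points = 40, seed = 1)
  cw <- synth_curve(spec2)
  expect_equal(cw$W, 1 - 0.5 * cw$u^1.5)
})
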