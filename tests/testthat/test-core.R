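test_that("thresholds and the normalized coordinate follow the slab geometry", {
  expect_equal(unname(thresholds(system_spec(1, 1, 2))), c(4, 16))
  expect_equal(unname(thresholds(system_spec(10, 0.8, 1))), c(0.256, 4))
  expect_equal(unname(thresholds(system_spec(5, 0, 1))), c(0, 4))
  sys <- system_spec(10, 0.8, 1)
  th <- thresholds(sys)
  expect_equal(normalized_u(th[["c1"]], sys), 0)
  expect_equal(normalized_u(th[["c2"]], sys), 1)
  expect_equal(normalized_u(0.58, sys), (0.58 - 0.256) / 3.744)
  for (i in 1:20) {
    N <- sample(1:50, 1); lam <- runif(1, 0, 0.95)
    s <- system_spec(N, lam, 1)
    th <- thresholds(s)
    expect_lte(th[["c1"]], th[["c2"]])
    expect_equal(s$K, s$D * (s$D + 1) / 2)
  }
  expect_error(system_spec(2, 1, 1), "d1 < d2")
})

test_that("instantaneous conformation tensor is the symmetric PSD second moment", {
  s11 <- system_spec(1, 0, 1)
  expect_equal(instantaneous_conformation(matrix(2, 1, 1), s11)[1, 1], 4)
  s12 <- system_spec(2, 0, 1)
  expect_equal(instantaneous_conformation(matrix(c(1, 1), 1, 2), s12)[1, 1], 1)
  s22 <- system_spec(2, 0, 1, D = 2)
  X <- cbind(c(1, 0), c(0, 1))
  expect_equal(instantaneous_conformation(X, s22),
               diag(0.5, 2))
  set.seed(7)
  for (i in 1:10) {
    D <- sample(2:4, 1); N <- sample(2:8, 1)
    s <- system_spec(N, 0, 1, D = D)
    X <- matrix(rnorm(D * N), D, N)
    ct <- instantaneous_conformation(X, s)
    expect_equal(ct, t(ct))
    expect_gte(min(eigen(ct, symmetric = TRUE)$values), -1e-12)
    expect_equal(ct[1, 1], sum(X[1, ]^2) / N)
  }
  expect_error(instantaneous_conformation(matrix(0, 3, 2), s22), "D x N")
})

test_that("unconfined partition function and its D = 1 reduction", {
  expect_equal(unconfined_partition(4, system_spec(3, 0, 1)), 2)
  expect_equal(unconfined_partition(7.3, system_spec(2, 0.25, 1)), 0.75^2)
  expect_equal(unconfined_partition(diag(2), system_spec(10, 0.8, 1, D = 2)),
               0.2^10)
  for (N in c(1, 2, 5)) {
    s <- system_spec(N, 0.3, 1.2)
    cval <- 0.7
    expect_equal(unconfined_partition(cval, s),
                 (1.2 - 0.3)^N * cval^((N - 2) / 2))
  }
  expect_error(unconfined_partition(0, system_spec(1, 0, 1)), "diverges")
})

test_that("entropy change is ln W in k_B units with a forbidden sentinel", {
  expect_equal(entropy_change(1), 0)
  expect_equal(entropy_change(0.5), log(0.5), tolerance = 1e-12)
  expect_identical(entropy_change(0), -Inf)
  expect_true(all(entropy_change(runif(20)) <= 0))
  expect_error(entropy_change(1.2), "\\[0, 1\\]")
})

test_that("anisotropic rescaling leaves u and W invariant", {
  s <- system_spec(3, 1, 2)
  r0 <- rescale(4, s, 1)
  expect_equal(r0$c, 4)
  expect_equal(r0$system$d2, 2)
  r <- rescale(4, s, 2)
  expect_equal(r$c, 1)
  expect_equal(c(r$system$d1, r$system$d2), c(0.5, 1))
  # u invariance for D = 1
  set.seed(11)
  for (i in 1:10) {
    sfac <- runif(1, 0.2, 5); cval <- runif(1, 0, 4)
    sys <- system_spec(2, 0.8, 1)
    rr <- rescale(cval, sys, sfac)
    expect_equal(normalized_u(cval, sys), normalized_u(rr$c, rr$system),
                 tolerance = 1e-12)
  }
  # exact W invariance of the closed-form and quadrature oracles
  for (cval in c(0.3, 1, 3.5)) {
    expect_equal(w_exact_n1(cval, 0.5, 1),
                 w_exact_n1(cval / 4, 0.25, 0.5), tolerance = 1e-13)
    rr <- rescale(cval, sys_n2_l08, 2)
    expect_equal(w_quadrature(cval, sys_n2_l08),
                 w_quadrature(rr$c, rr$system), tolerance = 1e-11)
  }
  # D = 2 tensor form
  s2 <- system_spec(4, 0.5, 1, D = 2)
  cm <- matrix(c(2, 0.3, 0.3, 1), 2)
  rr <- rescale(cm, s2, c(2, 3))
  expect_equal(rr$c, cm / tcrossprod(c(2, 3)))
  expect_error(rescale(cm, s2, c(1, -1)), "positive")
})

test_that("limit exponents obey beta = 4 alpha - 3", {
  ex <- limit_exponents(c(1, 2, 10))
  expect_equal(ex$alpha, c(1, 1.5, 5.5))
  expect_equal(ex$beta, c(1, 3, 19))
  all_n <- limit_exponents(1:60)
  expect_equal(all_n$beta, 4 * all_n$alpha - 3)
})

test_that("onset and saturation limit laws reduce to the N = 1 closed form", {
  g1 <- gamma_constants(1, 1 / 8, 1 / 4)
  s <- system_spec(1, 0.5, 1)
  th <- thresholds(s)
  expect_equal(onset_w_limit(th[["c1"]], s, g1), 1)
  expect_equal(saturation_w_limit(th[["c2"]], s, g1), 0)
  for (dc in c(1e-6, 1e-4)) {
    expect_equal(onset_w_limit(th[["c1"]] + dc, s, g1),
                 w_exact_n1(th[["c1"]] + dc, 0.5, 1),
                 tolerance = 1e-3 * sqrt(dc))
    expect_equal(saturation_w_limit(th[["c2"]] - dc, s, g1),
                 w_exact_n1(th[["c2"]] - dc, 0.5, 1),
                 tolerance = 1e-3 * sqrt(dc))
  }
  expect_error(onset_w_limit(0.1, system_spec(1, 0, 1), g1), "d1 > 0")
  # clamping far outside the expansion window
  g2 <- gamma_constants(2, 0.15, 0.0033)
  s2 <- system_spec(2, 0.8, 1)
  expect_true(all(onset_w_limit(thresholds(s2)[["c1"]] + seq(0, 2.7, 0.5),
                                s2, g2) >= 0))
  expect_true(all(saturation_w_limit(seq(0.1, 4, 0.5), s2, g2) <= 1))
})

test_that("interpolating propositions: endpoints, midpoint, limiting slopes", {
  p1 <- interp_params(1, 1, 1, 1, 1, 1)
  expect_equal(interp_w(c(0, 0.5, 1), p1), c(1, 0.5, 0))
  set.seed(13)
  for (i in 1:8) {
    pr <- sample(1:2, 1)
    pars <- runif(5, 1, 2.5)
    p <- interp_params(pr, pars[1], pars[2], pars[3], pars[4], pars[5])
    expect_equal(interp_w(0, p), 1)
    expect_equal(interp_w(1, p), 0)
    u0 <- 1e-4
    lead0 <- if (pr == 1) {
      pars[1] * pars[3]^pars[4] * pars[5] * u0^pars[4]
    } else {
      pars[1] * pars[5] * u0^pars[4]
    }
    expect_equal((1 - interp_w(u0, p)) / lead0, 1, tolerance = 0.01)
    u1 <- 1 - 1e-4
    lead1 <- if (pr == 1) {
      pars[1]^(-pars[5]) * (1 - u1)^(pars[2] * pars[5])
    } else {
      pars[1]^(-pars[5]) * pars[3]^(pars[2] * pars[5]) *
        (1 - u1)^(pars[2] * pars[5])
    }
    expect_equal(interp_w(u1, p) / lead1, 1, tolerance = 0.01)
  }
  expect_error(interp_w(1.5, p1), "\\[0, 1\\]")
  expect_error(interp_params(1, -1, 1, 1, 1), "positive")
})

test_that("entropic driving-force limits have the right shape", {
  s <- system_spec(1, 0.5, 1)
  th <- thresholds(s)
  f <- driving_force_limit(th[["c1"]] + c(0.01, 0.2), s, "onset_positive_d1")
  expect_equal(f[1], f[2])  # exponent (N-1)/2 = 0
  s0 <- system_spec(2, 0, 1)
  f2 <- driving_force_limit(c(0.01, 0.04), s0, "onset_zero_d1",
                            alpha_sim = 0.50)
  expect_equal(f2[1] / f2[2], (0.01 / 0.04)^(-0.5), tolerance = 1e-12)
  f3 <- driving_force_limit(c(3.9, 3.99, 3.999), s0, "saturation")
  expect_true(all(diff(abs(f3)) > 0))
  expect_true(all(c(f, f2, f3) < 0))
  expect_silent(driving_force_limit(0.1, s, "saturation"))
  expect_error(driving_force_limit(4.5, s0, "saturation"), "c2")
  expect_error(driving_force_limit(0.5, s, "onset_zero_d1"), "d1 = 0")
})

test_that("ball/cube volume fractions: exact low-N values and log-space stability", {
  expect_equal(ball_cube_fraction(1, "cube_in_ball"), 1)
  expect_equal(ball_cube_fraction(1, "ball_in_cube"), 1)
  expect_equal(ball_cube_fraction(2, "cube_in_ball"), 2 / pi)
  expect_equal(ball_cube_fraction(2, "ball_in_cube"), pi / 4)
  # direct product evaluation agrees with the log-space path at moderate N
  for (N in c(3, 6, 12, 20)) {
    ball_vol <- pi^(N / 2) / gamma(N / 2 + 1)
    expect_equal(ball_cube_fraction(N, "cube_in_ball"),
                 (2 / sqrt(N))^N / ball_vol, tolerance = 1e-12)
    expect_equal(ball_cube_fraction(N, "ball_in_cube"),
                 ball_vol / 2^N, tolerance = 1e-12)
  }
  expect_true(is.finite(ball_cube_fraction(1000, "ball_in_cube")))
})

test_that("normalized prefactors a, b are consistent with the limit laws", {
  g1 <- gamma_constants(1, 1 / 8, 1 / 4)
  s <- system_spec(1, 0.5, 1)
  tp <- theoretical_prefactors(s, g1)
  th <- thresholds(s)
  for (u in c(1e-4, 1e-3)) {
    cval <- th[["c1"]] + u * (th[["c2"]] - th[["c1"]])
    expect_equal(1 - onset_w_limit(cval, s, g1), tp$a * u^1,
                 tolerance = 1e-10)
    cval2 <- th[["c2"]] - u * (th[["c2"]] - th[["c1"]])
    expect_equal(saturation_w_limit(cval2, s, g1), tp$b * u^1,
                 tolerance = 1e-10)
  }
  expect_true(tp$a > 0 && tp$b > 0)
  # lambda = 0: onset prefactor undefined, saturation one still reported
  tp0 <- theoretical_prefactors(system_spec(1, 0, 1), g1)
  expect_true(is.na(tp0$a) && tp0$b > 0)
})
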