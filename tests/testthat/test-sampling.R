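test_that("direct estimator reproduces N = 1 bin-averaged closed form", {
  crv <- sample_direct(sys_n1, sampler_config(1e6, seed = 3))
  edges <- seq(0, 4, length.out = 101)
  truth <- n1_bin_W_curve(edges, 0, 1)
  ok <- is.finite(crv$W)
  z <- abs(crv$W - truth)[ok] / pmax(crv$SE[ok], 1e-9)
  expect_true(all(z < 4))
  expect_lt(mean(z), 1.2)
  # curve container invariants hold on sampled output
  expect_silent(validate_partition_curve(crv))
})

test_that("a window entirely below c1 gives W = 1 exactly", {
  sys <- system_spec(4, 0.8, 1)  # c1 = 0.64
  crv <- sample_direct(sys, sampler_config(2e5, seed = 5,
                                           c_window = c(0, 0.5),
                                           n_bins = 20))
  ok <- is.finite(crv$W)
  expect_true(all(crv$W[ok] == 1))
  expect_identical(crv$n_accepted[ok], crv$n_total[ok])
})

test_that("direct estimator agrees with the N = 2 quadrature oracle", {
  crv <- sample_direct(sys_n2_l08, sampler_config(1e6, seed = 7))
  truth <- w_quad_vec(crv$c, sys_n2_l08)
  ok <- is.finite(crv$W) & crv$n_total > 500
  # 3.5 SE plus a small allowance for the bin-center convention
  expect_true(all(abs(crv$W - truth)[ok] <=
                    3.5 * crv$SE[ok] + 2e-3))
})

test_that("shell estimator: exact limits and the N = 1 half-way value", {
  sys <- system_spec(3, 0.8, 1)  # c1 = 0.8533
  sh <- sample_shell(sys, c(0.3, 0.7, 4.2, 4.9), n_per_point = 2000,
                     seed = 9)
  expect_equal(sh$W[1:2], c(1, 1))   # below c1: every draw admissible
  expect_equal(sh$W[3:4], c(0, 0))   # above c2: no admissible state
  sh1 <- sample_shell(sys_n1, 1, n_per_point = 1e5, seed = 10)
  expect_equal(sh1$W, 0.5, tolerance = 3 * sh1$SE / 0.5)
  expect_error(sample_shell(sys_n1, c(-1, 1), 10), "positive")
})

test_that("direct and shell estimators agree on a common grid", {
  sys <- system_spec(3, 0, 1)
  crv <- sample_direct(sys, sampler_config(5e5, seed = 12,
                                           c_window = c(0.5, 3.5),
                                           n_bins = 25))
  sh <- sample_shell(sys, crv$c, n_per_point = 2e4, seed = 13)
  ok <- is.finite(crv$W)
  comb <- sqrt(crv$SE^2 + sh$SE^2)
  expect_true(all(abs(crv$W - sh$W)[ok] <= 3 * comb[ok] + 2e-3))
})

test_that("sampled curves are monotone non-increasing within noise", {
  sys <- sys_n2_l0
  cs <- seq(0.1, 3.9, length.out = 40)
  sh <- sample_shell(sys, cs, n_per_point = 4e4, seed = 15)
  expect_true(all(sh$SE < 0.005))
  iso <- stats::isoreg(sh$u, -sh$W)  # fits non-decreasing to -W
  dist <- max(abs(-iso$yf - sh$W))
  expect_lt(dist, 3 * mean(sh$SE) + 1e-12)
})

test_that("sampling respects the scaling relation", {
  cs <- c(0.5, 1.5, 3)
  a <- sample_shell(system_spec(2, 0.4, 1), cs, 2e4, seed = 17)
  b <- sample_shell(system_spec(2, 0.8, 2), 4 * cs, 2e4, seed = 17)
  comb <- sqrt(a$SE^2 + b$SE^2)
  expect_true(all(abs(a$W - b$W) <= 2 * pmax(comb, 1e-12)))
  d <- sample_shell(system_spec(2, 0.8, 2), 4 * cs, 2e4, seed = 18)
  expect_true(all(abs(a$W - d$W) <= 3 * sqrt(a$SE^2 + d$SE^2) + 1e-3))
})

test_that("partition-curve invariants are enforced", {
  sys <- sys_n2_l0
  expect_error(partition_curve(c(1, 2), c(0.5, 0.25), c(0.5, 0.4),
                               system = sys), "strictly increasing")
  expect_error(partition_curve(c(1, 2), c(0.25, 0.5), c(-0.1, 0.4),
                               system = sys), "W must be >= 0")
  expect_error(partition_curve(c(1, 2), c(0.25, 0.5), c(1.2, 0.4), SE = 0,
                               system = sys), "exceeds 1")
  # a relative curve may exceed 1
  expect_silent(partition_curve(c(1, 2), c(0.25, 0.5), c(1.2, 0.4),
                                system = sys, absolute = FALSE))
})

test_that("admissible mask keeps only bins fully inside det(c) >= 0", {
  c11 <- 0.5; c22m <- 4
  e12 <- seq(-sqrt(c11 * c22m), sqrt(c11 * c22m), length.out = 21)
  e22 <- seq(0, c22m, length.out = 21)
  m <- admissible_mask(c11, c22m, e12, e22)
  expect_true(m[10, 20])            # central c12, high c22
  expect_false(m[1, 1])             # extreme c12, low c22: below parabola
  expect_false(m[11, 1])            # bin touching the origin is excluded
  # every retained bin's worst corner satisfies the constraint
  for (i in seq_len(20)) for (j in seq_len(20)) {
    if (m[i, j]) {
      worst <- max(e12[i]^2, e12[i + 1]^2) / c11
      expect_gte(e22[j], worst)
    }
  }
})

test_that("factorization grid: wall disabled gives unit ratios; small run matches theory", {
  sysv <- system_spec(4, 0.8, 1, D = 2)
  g0 <- verify_2d(1.5, sysv, cfg = sampler_config(1e5, seed = 19),
                  wall_check = FALSE)
  vals <- g0$ratio[g0$mask & g0$n_free > 0]
  expect_true(all(vals == 1))
  expect_equal(g0$sigma_ratio, 0)
  sysv10 <- system_spec(10, 0.8, 1, D = 2)
  g <- verify_2d(0.58, sysv10, cfg = sampler_config(3e5, seed = 20))
  expect_equal(g$mean_ratio, 0.8998,
               tolerance = 3 * sqrt(g$se_mean^2 + 0.0017^2) / 0.9)
  expect_equal(g$c12_max, sqrt(0.58 * 4))
})
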