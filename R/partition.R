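#' Unconfined partition function G0
#'
#' Configurational partition function of `N` dumbbells at fixed conformation
#' tensor `c` in the absence of the wall:
#' `G0 = (d2 - d1)^N * det(c)^((N - D - 1)/2)`.
#' For `D = 1` this reduces to `(d2 - d1)^N * c^((N - 2)/2)`.
#'
#' @param c conformation tensor (`D x D` matrix, or scalar for D = 1).
#' @param system a [system_spec()].
#' @return Positive scalar (in length^(N + D(N - D - 1)) units).
#' @export
unconfined_partition <- function(c, system) {
  cm <- as_conformation_matrix(c, system$D)
  dc <- det(cm)
  expo <- (system$N - system$D - 1) / 2
  if (dc <= 0) {
    if (expo < 0) stop("det(c) = 0 with negative exponent: G0 diverges")
    if (expo == 0) return((system$d2 - system$d1)^system$N)
    return(0)
  }
  (system$d2 - system$d1)^system$N * dc^expo
}

#' Confinement-induced configurational entropy change
#'
#' `Delta S_c = ln(W)` in units of k_B. A forbidden conformation (`W = 0`)
#' is signalled by `-Inf`, the forbidden sentinel, distinguishable from any
#' finite entropy change.
#'
#' @param W partition coefficient(s) in \[0, 1\].
#' @return Numeric vector, `<= 0`, in units of k_B; `-Inf` where `W = 0`.
#' @export
entropy_change <- function(W) {
  if (any(W < 0 | W > 1, na.rm = TRUE)) stop("W must lie in [0, 1]")
  ifelse(W == 0, -Inf, log(W))
}

#' Limit-law exponents alpha and beta
#'
#' The onset of confinement follows `1 - W ~ a * u^alpha` with
#' `alpha = (N + 1)/2`, and the saturation follows `W ~ b * (1 - u)^beta`
#' with `beta = 2N - 1 = 4*alpha - 3`.
#'
#' @param N integer number(s) of dumbbells, >= 1.
#' @return data.frame with columns `N`, `alpha`, `beta`.
#' @export
limit_exponents <- function(N) {
  N <- as.integer(N)
  if (any(N < 1L)) stop("N must be >= 1")
  data.frame(N = N, alpha = (N + 1) / 2, beta = 2 * N - 1)
}

#' Prefactor constants of the onset and saturation limit laws
#'
#' Container for the dimensionless N-dependent prefactors `gamma_N` (onset)
#' and `gamma_check_N` (saturation). These constants are estimated
#' numerically by [estimate_gammas()]; the only analytically asserted
#' values are `gamma_1 = 1/8` and `gamma_check_1 = 1/4` (from the N = 1
#' closed form).
#'
#' @param N integer number of dumbbells.
#' @param gamma_N onset prefactor, > 0.
#' @param gamma_check_N saturation prefactor, > 0.
#' @param rel_tol relative estimation tolerance attached to the values.
#' @return Object of class `"gamma_constants"`.
#' @export
gamma_constants <- function(N, gamma_N, gamma_check_N, rel_tol = NA_real_) {
  if (!is.na(gamma_N) && gamma_N <= 0) stop("gamma_N must be > 0")
  if (!is.na(gamma_check_N) && gamma_check_N <= 0)
    stop("gamma_check_N must be > 0")
  structure(list(N = as.integer(N), gamma_N = gamma_N,
                 gamma_check_N = gamma_check_N, rel_tol = rel_tol),
            class = "gamma_constants")
}

#' @export
print.gamma_constants <- function(x, ...) {
  cat(sprintf("Limit-law prefactors for N = %d:\n", x$N))
  cat(sprintf("  gamma_N       = %.8g  (onset)\n", x$gamma_N))
  cat(sprintf("  gamma_check_N = %.8g  (saturation)\n", x$gamma_check_N))
  if (!is.na(x$rel_tol))
    cat(sprintf("  relative tolerance ~ %.2g\n", x$rel_tol))
  invisible(x)
}

#' Leading-order partition coefficient at the onset of confinement
#'
#' For `c` slightly above `c1` (and `d1 > 0`):
#' `W ~ 1 - gamma_N * (c - c1)^((N+1)/2) / (d1^N * (d2 - d1))`.
#' The leading-order expansion can overshoot outside its window, so the
#' result is clamped to \[0, 1\].
#'
#' @param c conformation value(s), `c >= c1`.
#' @param system a [system_spec()] with `d1 > 0`.
#' @param gammas a [gamma_constants()] for this `N`.
#' @return Partition coefficient value(s) in \[0, 1\]; exactly 1 at `c = c1`.
#' @export
onset_w_limit <- function(c, system, gammas) {
  if (system$d1 <= 0)
    stop("onset limit law requires d1 > 0 (no prediction for d1 = 0)")
  stopifnot(gammas$N == system$N)
  dc <- c - thresholds(system)[["c1"]]
  if (any(dc < 0)) stop("onset limit law requires c >= c1")
  w <- 1 - gammas$gamma_N * dc^((system$N + 1) / 2) /
    (system$d1^system$N * (system$d2 - system$d1))
  pmin(1, pmax(0, w))
}

#' Leading-order partition coefficient at the saturation of confinement
#'
#' For `c` slightly below `c2`:
#' `W ~ (N * gamma_check_N / 2^N) * (c2 - c)^(2N-1) /
#'      (d2^(3N-2) * (d2 - d1)^N)`.
#' Clamped to \[0, 1\]; exactly 0 at `c = c2`.
#'
#' @inheritParams onset_w_limit
#' @param c conformation value(s), `c <= c2`.
#' @return Partition coefficient value(s) in \[0, 1\].
#' @export
saturation_w_limit <- function(c, system, gammas) {
  stopifnot(gammas$N == system$N)
  N <- system$N
  dc <- c - thresholds(system)[["c2"]]
  if (any(dc > 0)) stop("saturation limit law requires c <= c2")
  w <- (N * gammas$gamma_check_N / 2^N) * (-dc)^(2 * N - 1) /
    (system$d2^(3 * N - 2) * (system$d2 - system$d1)^N)
  pmin(1, pmax(0, w))
}

#' Interpolating-function parameters
#'
#' Parameters of the two proposed closed-form representations of `W(u)`
#' over the full transition window (see [interp_w()]). All parameters must
#' be positive, which guarantees `W(0) = 1` and `W(1) = 0`.
#'
#' @param proposition 1 or 2, selecting the functional form.
#' @param g0,gamma1,gamma2,gamma3 positive dimensionless parameters.
#' @param gamma4 positive outer exponent; fixed to 1 in the reference fits.
#' @return Object of class `"interp_params"`.
#' @export
interp_params <- function(proposition, g0, gamma1, gamma2, gamma3,
                          gamma4 = 1) {
  proposition <- as.integer(proposition)
  if (!proposition %in% c(1L, 2L)) stop("proposition must be 1 or 2")
  p <- c(g0 = g0, gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
         gamma4 = gamma4)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all interpolation parameters must be positive")
  structure(list(proposition = proposition, g0 = g0, gamma1 = gamma1,
                 gamma2 = gamma2, gamma3 = gamma3, gamma4 = gamma4),
            class = "interp_params")
}

#' Interpolating partition-coefficient functions
#'
#' Two candidate closed forms bridging `W(0) = 1` to `W(1) = 0`:
#' proposition 1,
#' `W = ((1-u)^g1 / ((1-u)^g1 + g0 (1 - (1-u)^g2)^g3))^g4`,
#' and proposition 2,
#' `W = ((1-u^g2)^g1 / ((1-u^g2)^g1 + g0 u^g3))^g4`.
#' Near `u = 0` they behave as `1 - g0 g2^g3 g4 u^g3` (prop. 1) /
#' `1 - g0 g4 u^g3` (prop. 2); near `u = 1` both decay as
#' `const * (1-u)^(g1 g4)`.
#'
#' @param u normalized conformation coordinate(s) in \[0, 1\].
#' @param params an [interp_params()].
#' @return `W(u)` values in \[0, 1\].
#' @export
interp_w <- function(u, params) {
  stopifnot(inherits(params, "interp_params"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  p <- params
  if (p$proposition == 1L) {
    num <- (1 - u)^p$gamma1
    den <- num + p$g0 * (1 - (1 - u)^p$gamma2)^p$gamma3
  } else {
    num <- (1 - u^p$gamma2)^p$gamma1
    den <- num + p$g0 * u^p$gamma3
  }
  w <- ifelse(den == 0, 0, (num / den)^p$gamma4)
  pmin(1, pmax(0, w))
}

#' Confinement driving-force limits
#'
#' Proportional form of the entropic driving force
#' `d(Delta S_c)/dc` in the three limiting regimes: approach of `c1` with
#' `d1 > 0` (`-(c - c1)^((N-1)/2)`, finite), approach of `c = 0` for a
#' wall-adjacent slab `d1 = 0` (`-c^(alpha_sim - 1)`, divergent for
#' `alpha_sim < 1`), and approach of `c2` (`-1/(c2 - c)`, divergent).
#' Returned values are proportional to the driving force, not absolute.
#'
#' @param c conformation value(s) inside the regime named by `case`.
#' @param system a [system_spec()].
#' @param case one of `"onset_positive_d1"`, `"onset_zero_d1"`,
#'   `"saturation"`.
#' @param alpha_sim onset exponent for the `d1 = 0` case (default 0.50, the
#'   value the numerical onset fits converge to).
#' @return Numeric vector, negative (zero only where the force vanishes).
#' @export
driving_force_limit <- function(c, system,
                                case = c("onset_positive_d1",
                                         "onset_zero_d1", "saturation"),
                                alpha_sim = 0.50) {
  case <- match.arg(case)
  th <- thresholds(system)
  switch(case,
    onset_positive_d1 = {
      if (system$d1 <= 0) stop("case onset_positive_d1 requires d1 > 0")
      if (any(c < th[["c1"]])) stop("c must be >= c1 in this regime")
      -(c - th[["c1"]])^((system$N - 1) / 2)
    },
    onset_zero_d1 = {
      if (system$d1 != 0) stop("case onset_zero_d1 requires d1 = 0")
      if (any(c <= 0)) stop("c must be > 0 in this regime")
      -c^(alpha_sim - 1)
    },
    saturation = {
      if (any(c >= th[["c2"]])) stop("c must be < c2 in this regime")
      -1 / (th[["c2"]] - c)
    })
}

#' High-dimensional ball/cube volume fractions
#'
#' Volume fraction of an inscribed hypercube in the unit `N`-ball
#' (`mode = "cube_in_ball"`: `(2/sqrt(N))^N * Gamma(N/2 + 1) / pi^(N/2)`)
#' or of an inscribed ball in the unit hypercube
#' (`mode = "ball_in_cube"`: `pi^(N/2) / (2^N * Gamma(N/2 + 1))`).
#' Both collapse towards zero with growing `N`, which is why naive
#' rejection sampling starves in high dimension. Evaluated in log-space so
#' that e.g. `N = 100` does not underflow intermediates.
#'
#' @param N integer dimension(s), >= 1.
#' @param mode `"cube_in_ball"` or `"ball_in_cube"`.
#' @return Fraction(s) in (0, 1\].
#' @export
ball_cube_fraction <- function(N, mode = c("cube_in_ball", "ball_in_cube")) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  if (any(N < 1L)) stop("N must be >= 1")
  lf <- switch(mode,
    cube_in_ball = N * log(2 / sqrt(N)) + lgamma(N / 2 + 1) -
      (N / 2) * log(pi),
    ball_in_cube = (N / 2) * log(pi) - N * log(2) - lgamma(N / 2 + 1))
  exp(lf)
}

#' Theoretical limit-law prefactors a and b
#'
#' Converts the N-dependent constants `gamma_N`, `gamma_check_N` into the
#' prefactors of the normalized limit laws `1 - W ~ a u^alpha` and
#' `W ~ b (1-u)^beta`:
#' `a = 2^(N+1) gamma_N (1 - lambda^2/N)^((N+1)/2) / (lambda^N (1-lambda))`
#' (requires `lambda > 0`), and
#' `b = 2^(3N-2) N gamma_check_N (1 - lambda^2/N)^(2N-1) / (1-lambda)^N`.
#'
#' @param system a [system_spec()].
#' @param gammas a [gamma_constants()] for the same `N`.
#' @return List with `a`, `ln_a`, `b` (elements `NA` when undefined or the
#'   corresponding gamma is missing).
#' @export
theoretical_prefactors <- function(system, gammas) {
  stopifnot(gammas$N == system$N)
  N <- system$N; lam <- system$lambda
  base <- 1 - lam^2 / N
  a <- if (lam > 0 && !is.na(gammas$gamma_N)) {
    2^(N + 1) * gammas$gamma_N * base^((N + 1) / 2) / (lam^N * (1 - lam))
  } else NA_real_
  b <- if (!is.na(gammas$gamma_check_N)) {
    2^(3 * N - 2) * N * gammas$gamma_check_N * base^(2 * N - 1) /
      (1 - lam)^N
  } else NA_real_
  list(a = a, ln_a = if (is.na(a)) NA_real_ else log(a), b = b)
}
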