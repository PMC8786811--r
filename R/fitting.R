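#' Select the onset fitting window
#'
#' Window rule for the onset power law: the upper bound `c_hi` is the
#' largest bin with `W >= 0.99` (so all fitted values lie in
#' \[0.99, 1.00\]); the lower bound is chosen so that 90% of the window
#' lies above `c1`, i.e. `c_lo = c_hi - (c_hi - c1)/0.9`, reset to 0 when
#' negative (the `lambda = 0` case).
#'
#' @param curve a [partition_curve()] covering the onset region.
#' @param system a [system_spec()].
#' @return Named vector `c(c_lo, c_hi)`.
#' @export
select_onset_window <- function(curve, system) {
  th <- thresholds(system)
  ok <- which(is.finite(curve$W) & curve$W >= 0.99)
  if (!length(ok)) stop("no bin with W >= 0.99 in the curve")
  c_hi <- max(curve$c[ok])
  c_lo <- max(0, c_hi - (c_hi - th[["c1"]]) / 0.9)
  c(c_lo = c_lo, c_hi = c_hi)
}

new_powerlaw_fit <- function(regime, ln_a, exponent, ci95, R2, u_minus,
                             u_plus, n_bins, fit, absolute) {
  structure(list(regime = regime, ln_a = ln_a, exponent = exponent,
                 ci95 = ci95, R2 = R2, u_minus = u_minus, u_plus = u_plus,
                 range_ratio = u_plus / u_minus, n_bins = n_bins,
                 fit = fit, absolute = absolute),
            class = "powerlaw_fit")
}

#' Fit the onset power law 1 - W = a u^alpha
#'
#' Ordinary least squares of `ln(1 - W)` on `ln u` over the bins of the
#' curve with `0 < W < 1` and `u > 0` (bins with `W = 1` exactly carry no
#' log information and are excluded). The slope estimates the onset
#' exponent `alpha`, the intercept `ln a`; 95% confidence intervals come
#' from the regression t-distribution.
#'
#' @param curve a [partition_curve()] restricted to the onset window
#'   (see [select_onset_window()]).
#' @return Object of class `"powerlaw_fit"` with fields `ln_a`,
#'   `exponent`, `ci95` (named half-widths), `R2`, `u_minus`, `u_plus`,
#'   `range_ratio`.
#' @export
fit_onset <- function(curve) {
  use <- is.finite(curve$W) & curve$W > 0 & curve$W < 1 & curve$u > 0
  if (sum(use) < 3L) stop("fewer than 3 usable bins for the onset fit")
  lu <- log(curve$u[use])
  lw <- log(1 - curve$W[use])
  fit <- stats::lm(lw ~ lu)
  # exact oracle input is legitimate: silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  tq <- stats::qt(0.975, fit$df.residual)
  new_powerlaw_fit(
    regime = "onset", ln_a = stats::coef(fit)[[1]],
    exponent = stats::coef(fit)[[2]],
    ci95 = c(ln_a = tq * sm$coefficients[1, 2],
             exponent = tq * sm$coefficients[2, 2]),
    R2 = sm$r.squared, u_minus = min(curve$u[use]),
    u_plus = max(curve$u[use]), n_bins = sum(use), fit = fit,
    absolute = isTRUE(attr(curve, "absolute")))
}

#' Fit the saturation power law W = b (1 - u)^beta
#'
#' Ordinary least squares of `ln W` on `ln(1 - u)` over bins with
#' `W > 0` and `u < 1`. The slope estimates the saturation exponent
#' `beta`. The prefactor `b` is reported only for absolutely normalized
#' curves; a relative curve (e.g. a pure density-of-states histogram)
#' still determines the exponent.
#'
#' @param curve a [partition_curve()] covering the saturation window
#'   `[c2 (1 + eps), c2]`, `eps = -1e-3/N`.
#' @param system a [system_spec()] (used only for reporting; the fit acts
#'   on the `u` column).
#' @return Object of class `"powerlaw_fit"`; `ln_a` holds `ln b` when the
#'   input is absolute, `NA` otherwise. The `u_minus`/`u_plus` fields (and
#'   `range_ratio`) refer to the fitted `1 - u` values, matching how
#'   saturation fit ranges are reported.
#' @export
fit_saturation <- function(curve, system = attr(curve, "system")) {
  use <- is.finite(curve$W) & curve$W > 0 & curve$u < 1
  if (sum(use) < 3L) stop("fewer than 3 usable bins for the saturation fit")
  if (all(curve$W[use] == 0)) stop("all-zero W: nothing to fit")
  lv <- log(1 - curve$u[use])
  lw <- log(curve$W[use])
  fit <- stats::lm(lw ~ lv)
  # exact oracle input is legitimate: silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  tq <- stats::qt(0.975, fit$df.residual)
  absolute <- isTRUE(attr(curve, "absolute"))
  new_powerlaw_fit(
    regime = "saturation",
    ln_a = if (absolute) stats::coef(fit)[[1]] else NA_real_,
    exponent = stats::coef(fit)[[2]],
    ci95 = c(ln_a = if (absolute) tq * sm$coefficients[1, 2] else NA_real_,
             exponent = tq * sm$coefficients[2, 2]),
    R2 = sm$r.squared, u_minus = min(1 - curve$u[use]),
    u_plus = max(1 - curve$u[use]), n_bins = sum(use), fit = fit,
    absolute = absolute)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  lab <- if (x$regime == "onset") "alpha" else "beta"
  cat(sprintf("%s power-law fit over %d bins (u+/u- = %.4f):\n",
              x$regime, x$n_bins, x$range_ratio))
  cat(sprintf("  %s = %.4f +- %.4f (95%% CI)\n", lab, x$exponent,
              x$ci95[["exponent"]]))
  if (!is.na(x$ln_a))
    cat(sprintf("  ln %s = %.4f +- %.4f\n",
                if (x$regime == "onset") "a" else "b", x$ln_a,
                x$ci95[["ln_a"]]))
  cat(sprintf("  R^2 = %.6f\n", x$R2))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(ln_a = object$ln_a, exponent = object$exponent)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  out <- c(list(regime = object$regime), coef(object),
           list(ci95 = object$ci95, R2 = object$R2,
                u_minus = object$u_minus, u_plus = object$u_plus,
                range_ratio = object$range_ratio, n_bins = object$n_bins))
  class(out) <- "summary.powerlaw_fit"
  out
}

#' @export
print.summary.powerlaw_fit <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
predict.powerlaw_fit <- function(object, u, ...) {
  if (object$regime == "onset") {
    1 - exp(object$ln_a) * u^object$exponent
  } else {
    pref <- if (is.na(object$ln_a)) 1 else exp(object$ln_a)
    pref * (1 - u)^object$exponent
  }
}

#' @export
plot.powerlaw_fit <- function(x, curve = NULL, ...) {
  if (is.null(curve)) {
    m <- stats::model.frame(x$fit)
    plot(m[[2]], m[[1]], xlab = if (x$regime == "onset") "ln u"
         else "ln(1-u)", ylab = if (x$regime == "onset") "ln(1-W)"
         else "ln W", pch = 16, cex = 0.6, ...)
    graphics::abline(x$fit, col = 2)
  } else {
    plot(curve, log_w = TRUE, ...)
    graphics::lines(curve$u, log(predict(x, curve$u)), col = 2)
  }
  invisible(x)
}

# residual-vector evaluation for the interpolating fit, in log-parameter
# space (enforces positivity)
interp_residuals <- function(logp, u, W, proposition, gamma4) {
  p <- exp(logp)
  par <- interp_params(proposition, p[1], p[2], p[3], p[4], gamma4)
  interp_w(u, par) - W
}

#' Multi-start fit of the interpolating functions
#'
#' Nonlinear least squares of [interp_w()] (proposition 1 or 2) to a
#' full-range curve, with `gamma4` fixed to 1 by default and the free
#' parameters `g0, gamma1, gamma2, gamma3` restarted from `n_starts`
#' log-uniform random points in \[1e-3, 1e3\]^4. All converged solutions
#' are kept; distinct solutions are counted by relative parameter
#' distance > 1e-3, and the best (by residual sum of squares) is
#' reported together with `R2` and the relative L2 misfit
#' `eps_W = ||W - W_fit|| / ||W||` on the fitted grid.
#'
#' @param curve a [partition_curve()] spanning most of `u` in \[0, 1\].
#' @param proposition 1 or 2.
#' @param fix_gamma4 keep `gamma4 = 1` (default TRUE; FALSE adds it as a
#'   fifth free parameter).
#' @param n_starts number of random starts (default 32).
#' @param seed RNG seed for the starts.
#' @return Object of class `"interp_fit"`: `params` (an
#'   [interp_params()]), `R2`, `eps_W`, `n_starts`,
#'   `n_distinct_solutions`, `all_converged`, `solutions` (parameter
#'   matrix of distinct solutions), `poor` flag (`eps_W > 0.02`).
#' @export
fit_interp <- function(curve, proposition = 1L, fix_gamma4 = TRUE,
                       n_starts = 32L, seed = 1L) {
  use <- is.finite(curve$W)
  u <- curve$u[use]
  W <- curve$W[use]
  if (length(u) < 8L) stop("too few bins for the interpolating fit")
  set.seed(seed)
  npar <- if (fix_gamma4) 4L else 5L
  sols <- list()
  conv <- logical(0)
  resfun <- if (fix_gamma4) {
    function(lp) interp_residuals(lp, u, W, proposition, 1)
  } else {
    function(lp) {
      p <- exp(lp)
      interp_w(u, interp_params(proposition, p[1], p[2], p[3], p[4],
                                p[5])) - W
    }
  }
  for (s in seq_len(n_starts)) {
    # first start at unit parameters, then log-uniform random restarts
    start <- if (s == 1L) rep(0, npar)
             else stats::runif(npar, log(1e-3), log(1e3))
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) { conv <- c(conv, FALSE); next }
    ok <- res$info %in% 1:4
    conv <- c(conv, ok)
    if (ok) sols[[length(sols) + 1L]] <-
        c(exp(res$par), sum(res$fvec^2))
  }
  if (!length(sols)) stop("no start converged for the interpolating fit")
  m <- do.call(rbind, sols)
  m <- m[order(m[, npar + 1L]), , drop = FALSE]
  # distinct solutions by relative parameter distance
  distinct <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    d <- apply(distinct[, seq_len(npar), drop = FALSE], 1, function(p)
      max(abs(m[i, seq_len(npar)] - p) / pmax(abs(p), 1e-12)))
    if (min(d) > 1e-3) distinct <- rbind(distinct, m[i, ])
  }
  best <- distinct[1, ]
  params <- interp_params(proposition, best[1], best[2], best[3], best[4],
                          if (fix_gamma4) 1 else best[5])
  Wfit <- interp_w(u, params)
  ss_res <- sum((W - Wfit)^2)
  ss_tot <- sum((W - mean(W))^2)
  eps_W <- sqrt(ss_res) / sqrt(sum(W^2))
  structure(list(params = params, R2 = 1 - ss_res / ss_tot, eps_W = eps_W,
                 n_starts = n_starts,
                 n_distinct_solutions = nrow(distinct),
                 all_converged = all(conv),
                 solutions = distinct, poor = eps_W > 0.02,
                 u = u, W = W), class = "interp_fit")
}

#' Misfit of a fully pinned interpolating function
#'
#' Evaluates an interpolating proposition whose parameters are pinned by
#' the two limit laws (no free parameters, `gamma4 = 1`): for
#' proposition 1, `g0 = 1/b`, `gamma1 = beta`, `gamma3 = alpha`,
#' `gamma2 = (a b)^(1/alpha)`; the analogous identification for
#' proposition 2 (`gamma2 = 1` there, prefactor matching via `g0`). This
#' quantifies how poorly the limit-constrained forms represent the whole
#' curve.
#'
#' @param curve a full-range [partition_curve()].
#' @param a,b,alpha,beta limit-law constants (see
#'   [theoretical_prefactors()] and [limit_exponents()]).
#' @param proposition 1 or 2.
#' @return List with `params`, `eps_W`, `poor` (`eps_W > 0.02`).
#' @export
interp_limit_pinned <- function(curve, a, b, alpha, beta,
                                proposition = 1L) {
  params <- if (proposition == 1L) {
    interp_params(1, g0 = 1 / b, gamma1 = beta,
                  gamma2 = (a * b)^(1 / alpha), gamma3 = alpha, gamma4 = 1)
  } else {
    # prop. 2 limits: 1 - g0 u^g3 and g0^-1 g2^g1 (1-u)^g1; with gamma4 = 1
    # matching both prefactors requires gamma2^gamma1 = a b
    interp_params(2, g0 = a, gamma1 = beta,
                  gamma2 = (a * b)^(1 / beta), gamma3 = alpha, gamma4 = 1)
  }
  use <- is.finite(curve$W)
  Wfit <- interp_w(curve$u[use], params)
  eps_W <- sqrt(sum((curve$W[use] - Wfit)^2)) / sqrt(sum(curve$W[use]^2))
  list(params = params, eps_W = eps_W, poor = eps_W > 0.02)
}

#' @export
print.interp_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Interpolating fit, proposition %d (gamma4 = %g):\n",
              p$proposition, p$gamma4))
  cat(sprintf(
    "  g0 = %.5g, gamma1 = %.5g, gamma2 = %.5g, gamma3 = %.5g\n",
    p$g0, p$gamma1, p$gamma2, p$gamma3))
  cat(sprintf("  R^2 = %.6f, eps_W = %.3g%s\n", x$R2, x$eps_W,
              if (x$poor) " (poor)" else ""))
  cat(sprintf("  converged: %s (%d starts); %d distinct solution(s)\n",
              if (x$all_converged) "all" else "not all", x$n_starts,
              x$n_distinct_solutions))
  invisible(x)
}

#' @export
coef.interp_fit <- function(object, ...) {
  p <- object$params
  c(g0 = p$g0, gamma1 = p$gamma1, gamma2 = p$gamma2, gamma3 = p$gamma3,
    gamma4 = p$gamma4)
}

#' @export
predict.interp_fit <- function(object, u, ...) interp_w(u, object$params)

#' @export
plot.interp_fit <- function(x, ...) {
  plot(x$u, x$W, xlab = "u", ylab = "W", pch = 16, cex = 0.5, ...)
  uu <- seq(0, 1, length.out = 400)
  graphics::lines(uu, predict(x, uu), col = 2)
  invisible(x)
}

#' Serialize a fit result as JSON
#'
#' Writes regime/proposition, parameters, confidence intervals, fit
#' diagnostics, window bounds and an input-curve checksum to a JSON file.
#'
#' @param fit a `"powerlaw_fit"` or `"interp_fit"`.
#' @param path output path.
#' @param curve the fitted curve (optional, for the checksum).
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path, curve = NULL) {
  checksum <- if (!is.null(curve))
    sum(curve$W * seq_along(curve$W), na.rm = TRUE) else NA_real_
  out <- if (inherits(fit, "powerlaw_fit")) {
    list(type = "power_law", regime = fit$regime, ln_a = fit$ln_a,
         exponent = fit$exponent, ci95 = as.list(fit$ci95), R2 = fit$R2,
         u_minus = fit$u_minus, u_plus = fit$u_plus,
         range_ratio = fit$range_ratio, n_bins = fit$n_bins,
         curve_checksum = checksum)
  } else {
    list(type = "interp", proposition = fit$params$proposition,
         params = as.list(coef(fit)), R2 = fit$R2, eps_W = fit$eps_W,
         n_starts = fit$n_starts,
         n_distinct_solutions = fit$n_distinct_solutions,
         all_converged = fit$all_converged,
         solutions = apply(fit$solutions, 1, as.list),
         curve_checksum = checksum)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
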