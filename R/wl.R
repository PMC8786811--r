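#' Wang-Landau estimation of the log density of states over c
#'
#' Flat-histogram walk of `N` dumbbells (D = 1) in bead coordinates, with
#' 100 equally spaced bins on `[0, c2]` by default. A proposal perturbs a
#' randomly chosen bead coordinate by a uniform increment on
#' `[-step_half_width, step_half_width]`; moves leaving the admissible
#' domain (wall plus slab conditions) are rejected with the usual
#' re-increment of the current bin. The modification factor `ln f` starts
#' at 1 and halves whenever the visit histogram is flat
#' (`min(H) >= flatness * max(H)`, checked every `check_every` steps);
#' once the halved value would fall below `1/t` (with the Monte Carlo time
#' `t` = steps / bins), the schedule switches to `ln f = 1/t`, which
#' avoids the error saturation of the plain algorithm, and stops at
#' `lnf_final`.
#'
#' @param system a [system_spec()] with `D = 1`.
#' @param step_half_width half-width of the proposal increment, in units
#'   of `d2` (default 0.2).
#' @param flatness flatness threshold (default 0.8).
#' @param check_every steps between flatness checks (default 1000).
#' @param lnf_final terminal modification factor (default 1e-7).
#' @param seed integer RNG seed.
#' @param n_bins number of bins (default 100).
#' @param c_max upper end of the binned range; defaults to `c2`. Values
#'   above `c2` are allowed; such bins can never be visited and come back
#'   flagged.
#' @param max_steps hard cap on Monte Carlo steps; if reached before
#'   `lnf_final`, the partial state is returned with `converged = FALSE`.
#' @return Object of class `"wl_state"`: bin edges, `lnG` (up to one
#'   additive constant), final-stage and cumulative visit histograms,
#'   `ln_f`, the `ln f` trace, step count, stage, convergence flag, and
#'   the final walker configuration.
#' @export
wl_run <- function(system, step_half_width = 0.2, flatness = 0.8,
                   check_every = 1000L, lnf_final = 1e-7, seed = 1L,
                   n_bins = 100L, c_max = NULL, max_steps = 5e9) {
  stopifnot(inherits(system, "system_spec"), system$D == 1L)
  th <- thresholds(system)
  if (is.null(c_max)) c_max <- th[["c2"]]
  set.seed(seed)
  res <- wl_run_cpp(system$N, system$d1, system$d2, c_max,
                    as.integer(n_bins), step_half_width, flatness,
                    as.integer(check_every), 1.0, lnf_final, max_steps)
  if (!res$converged)
    warning("Wang-Landau run hit max_steps before reaching lnf_final; ",
            "partial state returned")
  structure(list(
    bin_edges = seq(0, c_max, length.out = n_bins + 1L),
    lnG = res$lnG, H = res$H, H_total = res$H_total, ln_f = res$ln_f,
    lnf_trace = res$lnf_trace, stage = res$stage, mc_steps = res$mc_steps,
    converged = res$converged,
    config = bead_configuration(matrix(res$y - res$x, 1L, system$N),
                                (res$x + res$y) / 2, system),
    system = system, seed = as.integer(seed),
    step_half_width = step_half_width, flatness = flatness,
    lnf_final = lnf_final
  ), class = "wl_state")
}

#' @export
print.wl_state <- function(x, ...) {
  cat(sprintf(
    "Wang-Landau state: N = %d, lambda = %g, %d bins on [0, %g]\n",
    x$system$N, x$system$lambda, length(x$lnG), max(x$bin_edges)))
  cat(sprintf(
    "  %s after %.3g steps; ln f = %.3g (%s), %d bins visited\n",
    if (x$converged) "converged" else "NOT converged", x$mc_steps,
    x$ln_f, x$stage, sum(x$H_total > 0)))
  invisible(x)
}

#' Reference walk with a frozen bias table
#'
#' Runs the same move set as [wl_run()] but with a fixed, user-supplied
#' `lnG` table and no updates. When the supplied table is the exact log
#' density of states, the visit histogram is asymptotically flat; this
#' validates the move set, detailed balance and the binning independently
#' of the Wang-Landau update rule.
#'
#' @inheritParams wl_run
#' @param lnG fixed per-bin log weights (length defines the bin count).
#' @param n_steps number of Monte Carlo steps.
#' @return Integer-valued visit histogram (length of `lnG`).
#' @export
wl_reference_walk <- function(system, lnG, n_steps, step_half_width = 0.2,
                              seed = 1L, c_max = NULL) {
  stopifnot(inherits(system, "system_spec"), system$D == 1L)
  if (is.null(c_max)) c_max <- thresholds(system)[["c2"]]
  set.seed(seed)
  wl_reference_walk_cpp(system$N, system$d1, system$d2, c_max,
                        as.numeric(lnG), step_half_width, n_steps)$H
}

# exact per-bin integral of G0(c) = (d2-d1)^N c^((N-2)/2) for D = 1
lnG0_bin_integral <- function(edges, system) {
  N <- system$N
  p <- N / 2
  N * log(system$d2 - system$d1) +
    log((edges[-1L]^p - edges[-length(edges)]^p) * 2 / N)
}

#' Convert a Wang-Landau state to a relative ln W curve
#'
#' Divides the estimated per-bin density of states by the analytically
#' known unconfined `G0` (its exact integral over each bin), giving
#' `ln W` up to a single additive constant. The curve is returned with
#' `W = exp(lnW)` normalized so its maximum is 1 and flagged
#' `absolute = FALSE`; bins never visited are `NA`.
#'
#' @param state a [wl_run()] result.
#' @param system the [system_spec()] (defaults to the one in `state`).
#' @return A [partition_curve()] with estimator `"wang-landau"`.
#' @export
wl_to_lnW <- function(state, system = state$system) {
  stopifnot(inherits(state, "wl_state"))
  visited <- state$H_total > 0
  if (!any(visited)) stop("no bin was ever visited")
  lnW <- state$lnG - lnG0_bin_integral(state$bin_edges, system)
  lnW[!visited] <- NA_real_
  lnW <- lnW - max(lnW, na.rm = TRUE)
  centers <- (state$bin_edges[-1L] +
                state$bin_edges[-length(state$bin_edges)]) / 2
  partition_curve(c = centers, u = normalized_u(centers, system),
                  W = exp(lnW), SE = 0, system = system,
                  estimator = "wang-landau", seed = state$seed,
                  absolute = FALSE,
                  extra = list(visited = visited,
                               mc_steps = state$mc_steps,
                               ln_f = state$ln_f))
}

#' Merge a relative Wang-Landau curve with an absolute direct curve
#'
#' Fixes the unknown additive constant of a Wang-Landau `ln W` curve using
#' an absolutely normalized direct-sampling curve. Where the two curves
#' overlap (direct bins with `SE(ln W) = SE/W` below `se_max`), the shift
#' is the mean of the pointwise differences. Where a gap separates them,
#' a quadratic bridge in `u` is constructed from three conditions: the
#' one-sided slopes on both sides of the gap (least-squares slopes over
#' `k_slope` bins) and the known absolute value at the left end; the
#' Wang-Landau branch is then shifted to continuity.
#'
#' @param wl_curve relative [partition_curve()] (from [wl_to_lnW()]).
#' @param direct_curve absolute [partition_curve()] (e.g. from
#'   [sample_direct()]).
#' @param se_max reliability threshold on `SE(ln W)` for direct bins
#'   (default 0.05).
#' @param k_slope bins per one-sided slope estimate in the gap case.
#' @return An absolute [partition_curve()] (estimator `"merged"`) covering
#'   the union of the reliable direct range and the Wang-Landau range,
#'   with any gap filled by the quadratic bridge.
#' @export
merge_curves <- function(wl_curve, direct_curve, se_max = 0.05,
                         k_slope = 5L) {
  stopifnot(!isTRUE(attr(wl_curve, "absolute")),
            isTRUE(attr(direct_curve, "absolute")))
  system <- attr(direct_curve, "system")
  dok <- which(is.finite(direct_curve$W) & direct_curve$W > 0 &
                 direct_curve$SE / direct_curve$W < se_max)
  if (!length(dok)) stop("direct curve has no reliable bin")
  wok <- which(is.finite(wl_curve$W) & wl_curve$W > 0)
  du <- direct_curve$u[dok]
  dln <- log(direct_curve$W[dok])
  wu <- wl_curve$u[wok]
  wln <- log(wl_curve$W[wok])
  overlap <- dok[du >= min(wu) & du <= max(wu)]
  if (length(overlap)) {
    wl_at <- stats::approx(wu, wln, xout = direct_curve$u[overlap])$y
    shift <- mean(log(direct_curve$W[overlap]) - wl_at)
    shift_se <- stats::sd(log(direct_curve$W[overlap]) - wl_at) /
      sqrt(length(overlap))
    bridge <- NULL
  } else {
    if (max(du) >= min(wu))
      stop("no overlap and no valid gap geometry between the curves")
    iL <- utils::tail(seq_along(du), k_slope)
    iR <- utils::head(seq_along(wu), k_slope)
    if (length(iL) < 2L || length(iR) < 2L)
      stop("too few bins to estimate one-sided slopes for the gap bridge")
    sL <- stats::coef(stats::lm(dln[iL] ~ du[iL]))[[2]]
    sR <- stats::coef(stats::lm(wln[iR] ~ wu[iR]))[[2]]
    uL_bar <- mean(du[iL]); uR_bar <- mean(wu[iR])
    u_star <- max(du); ln_star <- dln[length(dln)]
    # p'(u) linear through (uL_bar, sL), (uR_bar, sR); p anchored at u_star
    slope_fun <- function(u) sL + (sR - sL) * (u - uL_bar) / (uR_bar - uL_bar)
    p_fun <- function(u) {
      ln_star + sL * (u - u_star) +
        (sR - sL) / (uR_bar - uL_bar) *
          ((u - uL_bar)^2 - (u_star - uL_bar)^2) / 2
    }
    u_anchor <- wu[1L]
    shift <- p_fun(u_anchor) - wln[1L]
    shift_se <- NA_real_
    gap_u <- seq(u_star, min(wu), length.out = max(3L, k_slope))
    gap_u <- gap_u[-c(1L, length(gap_u))]
    bridge <- data.frame(u = gap_u, lnW = p_fun(gap_u))
  }
  th <- thresholds(system)
  keep_wl <- wok[wu > max(du) | wu < min(du)]
  out <- rbind(
    data.frame(u = du, lnW = dln, SE = direct_curve$SE[dok] /
                 direct_curve$W[dok], src = "direct"),
    if (!is.null(bridge))
      data.frame(u = bridge$u, lnW = bridge$lnW, SE = NA_real_,
                 src = "bridge"),
    data.frame(u = wl_curve$u[keep_wl], lnW = log(wl_curve$W[keep_wl]) +
                 shift,
               SE = if (is.na(shift_se)) NA_real_ else shift_se,
               src = "wang-landau"))
  out <- out[order(out$u), ]
  out <- out[!duplicated(out$u), ]
  W <- exp(pmin(out$lnW, 0))
  partition_curve(c = th[["c1"]] + out$u * (th[["c2"]] - th[["c1"]]),
                  u = out$u, W = W,
                  SE = ifelse(is.na(out$SE), 0, out$SE * W),
                  system = system, estimator = "merged",
                  seed = attr(direct_curve, "seed"), absolute = TRUE,
                  extra = list(shift = shift, shift_se = shift_se,
                               source = out$src,
                               bridged = !is.null(bridge)))
}
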