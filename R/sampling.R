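#' Monte Carlo sampler configuration
#'
#' @param n_cfg total number of sampled N-dumbbell configurations.
#' @param seed integer RNG seed.
#' @param c_window `c(c_lo, c_hi)` histogram window in length^2 (defaults
#'   to `c(0, c2)` when a system is supplied at sampling time).
#' @param n_bins number of equal-width, left-closed right-open bins on the
#'   c-axis (default 100).
#' @param batch_size configurations drawn per vectorized batch (bounds
#'   memory use).
#' @return Object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_cfg, seed = 1L, c_window = NULL,
                           n_bins = 100L, batch_size = 1e5) {
  n_cfg <- as.numeric(n_cfg)
  n_bins <- as.integer(n_bins)
  if (n_cfg < n_bins || n_bins < 1L) stop("need n_cfg >= n_bins >= 1")
  if (!is.null(c_window)) {
    if (length(c_window) != 2L || c_window[1] < 0 ||
        c_window[2] <= c_window[1])
      stop("c_window must be c(c_lo, c_hi) with 0 <= c_lo < c_hi")
  }
  structure(list(n_cfg = n_cfg, seed = as.integer(seed),
                 c_window = c_window, n_bins = n_bins,
                 batch_size = batch_size),
            class = "sampler_config")
}

#' Direct paired-histogram estimator of W(c)
#'
#' Samples connector vectors `X` uniformly in the N-ball of radius
#' `sqrt(N * c_hi)` (so that the reference histogram reproduces the
#' unconfined density of states, proportional to `c^((N-2)/2)`) and
#' center-of-mass coordinates `Y` uniformly in `[d1, d2]^N`. Two histograms
#' over the instantaneous `c = |X|^2/N` are accumulated: the reference one
#' counts every draw, the wall one only draws with `|X_mu| <= 2 Y_mu` for
#' all `mu`; their per-bin ratio is the absolutely normalized `W(c)`.
#'
#' @param system a [system_spec()] with `D = 1`.
#' @param cfg a [sampler_config()]; `c_window` defaults to `c(0, c2)` and
#'   must lie within `[0, c2]`.
#' @return A [partition_curve()] (estimator `"direct"`). Bins with no
#'   reference counts have `W = NA` and are listed in the `empty` metadata
#'   entry; bins with fewer than 100 reference counts are flagged
#'   low-confidence.
#' @export
sample_direct <- function(system, cfg) {
  stopifnot(inherits(system, "system_spec"), system$D == 1L,
            inherits(cfg, "sampler_config"))
  th <- thresholds(system)
  win <- if (is.null(cfg$c_window)) c(0, th[["c2"]]) else cfg$c_window
  if (win[2] > th[["c2"]] + 1e-12)
    stop("c_window must lie within [0, c2]")
  N <- system$N
  nb <- cfg$n_bins
  wid <- (win[2] - win[1]) / nb
  radius <- sqrt(N * win[2])
  H_free <- numeric(nb)
  H_wall <- numeric(nb)
  set.seed(cfg$seed)
  left <- cfg$n_cfg
  while (left > 0) {
    m <- as.integer(min(cfg$batch_size, left))
    left <- left - m
    Z <- matrix(stats::rnorm(m * N), m, N)
    rad <- radius * stats::runif(m)^(1 / N)
    X <- Z * (rad / sqrt(rowSums(Z^2)))
    c_hat <- rad^2 / N
    Y <- matrix(stats::runif(m * N, system$d1, system$d2), m, N)
    ok <- rowSums(abs(X) > 2 * Y) == 0L
    bin <- floor((c_hat - win[1]) / wid) + 1L
    inwin <- bin >= 1L & bin <= nb
    H_free <- H_free + tabulate(bin[inwin], nbins = nb)
    H_wall <- H_wall + tabulate(bin[inwin & ok], nbins = nb)
  }
  W <- ifelse(H_free > 0, H_wall / H_free, NA_real_)
  SE <- ifelse(H_free > 0, sqrt(pmax(W * (1 - W), 0) / pmax(H_free, 1)), NA_real_)
  centers <- win[1] + (seq_len(nb) - 0.5) * wid
  partition_curve(c = centers, u = normalized_u(centers, system),
                  W = W, SE = SE, n_accepted = H_wall, n_total = H_free,
                  system = system, estimator = "direct", seed = cfg$seed,
                  absolute = TRUE,
                  extra = list(n_cfg = cfg$n_cfg, c_window = win,
                               empty = which(H_free == 0),
                               low_confidence = which(H_free > 0 &
                                                        H_free < 100)))
}

#' Shell (fixed-c) acceptance estimator of W(c)
#'
#' For each requested `c`, draws `X` uniformly on the (N-1)-sphere of
#' radius `sqrt(N c)` and `Y` uniformly in `[d1, d2]^N`; the acceptance
#' fraction of the wall condition `|X_mu| <= 2 Y_mu` is an absolutely
#' normalized, unbiased estimate of `W(c)`. This is the stratified
#' counterpart of [sample_direct()]: every point receives the same number
#' of configurations, so the saturation regime does not starve.
#'
#' @param system a [system_spec()] with `D = 1`.
#' @param c_values strictly increasing conformation values in (0, c2\].
#' @param n_per_point configurations per c value.
#' @param seed integer RNG seed.
#' @param batch_size configurations per vectorized batch.
#' @return A [partition_curve()] (estimator `"shell"`).
#' @export
sample_shell <- function(system, c_values, n_per_point, seed = 1L,
                         batch_size = 1e5) {
  stopifnot(inherits(system, "system_spec"), system$D == 1L)
  th <- thresholds(system)
  if (any(c_values <= 0)) stop("c values must be positive")
  if (any(diff(c_values) <= 0)) stop("c_values must be strictly increasing")
  N <- system$N
  set.seed(seed)
  acc <- numeric(length(c_values))
  for (i in seq_along(c_values)) {
    if (c_values[i] > th[["c2"]]) next  # no admissible state: W = 0
    radius <- sqrt(N * c_values[i])
    left <- n_per_point
    while (left > 0) {
      m <- as.integer(min(batch_size, left))
      left <- left - m
      Z <- matrix(stats::rnorm(m * N), m, N)
      X <- Z * (radius / sqrt(rowSums(Z^2)))
      Y <- matrix(stats::runif(m * N, system$d1, system$d2), m, N)
      acc[i] <- acc[i] + sum(rowSums(abs(X) > 2 * Y) == 0L)
    }
  }
  W <- acc / n_per_point
  partition_curve(c = c_values, u = normalized_u(c_values, system),
                  W = W, SE = sqrt(W * (1 - W) / n_per_point),
                  n_accepted = acc, n_total = rep(n_per_point,
                                                  length(c_values)),
                  system = system, estimator = "shell", seed = seed,
                  absolute = TRUE,
                  extra = list(n_per_point = n_per_point))
}
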