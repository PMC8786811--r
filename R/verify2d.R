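#' Admissible-bin mask for the D = 2 verification grid
#'
#' A bin of the `(c12, c22)` histogram is retained only if it lies
#' entirely inside the admissible conformation domain `det(c) >= 0`, i.e.
#' all four corners satisfy `c22 >= c12^2 / c11`. The domain boundary is
#' the parabola `c22/c22_max = (c12/c12_max)^2` with
#' `c12_max = sqrt(c11 * c22_max)`.
#'
#' @param c11 fixed wall-normal component (length^2).
#' @param c22_max upper edge of the `c22` axis.
#' @param c12_edges,c22_edges bin edge vectors covering
#'   `[-c12_max, c12_max]` and `[0, c22_max]`.
#' @return Logical matrix, rows indexing `c12` bins, columns `c22` bins.
#' @export
admissible_mask <- function(c11, c22_max, c12_edges, c22_edges) {
  n12 <- length(c12_edges) - 1L
  n22 <- length(c22_edges) - 1L
  worst <- pmax(c12_edges[-length(c12_edges)]^2, c12_edges[-1L]^2) / c11
  outer(worst, c22_edges[-length(c22_edges)],
        function(w, lo) lo >= w)[, seq_len(n22), drop = FALSE]
}

#' D = 2 factorization verification sampler
#'
#' Verifies that for `D > 1` the wall affects the partition function only
#' through the wall-normal component: `G(c) = W(c11) * G0(c)`. At fixed
#' `c11`, draws `X1` uniformly on the sphere of radius `sqrt(N c11)` and
#' `X2` uniformly inside the ball of radius `sqrt(N c22_max)`; every draw
#' updates the unconfined histogram over `(c12, c22)`, and draws that
#' additionally satisfy the wall condition `|X1_mu| <= 2 Y_mu` (with `Y`
#' uniform in `[d1, d2]^N`) update the confined histogram. The per-bin
#' ratio estimates `G/G0` and should be flat at the value `W(c11)` from
#' the 1-D theory; the mean and standard deviation are taken over bins
#' entirely inside the admissible domain.
#'
#' @param c11 fixed wall-normal conformation component, in `(c1, c2]`.
#' @param system a [system_spec()] with `D = 2` (N gives the dumbbell
#'   count).
#' @param c22_max upper edge of the `c22` axis; defaults to `c2 = 4 d2^2`.
#' @param n_bins_2d bins per axis (default 20).
#' @param cfg a [sampler_config()] (its `c_window`/`n_bins` are ignored).
#' @param wall_check set `FALSE` to disable the wall condition (debug
#'   mode: every ratio becomes 1).
#' @return Object of class `"verify2d_grid"`: bin centers, per-bin ratio
#'   matrix and counts, admissible mask, `mean_ratio`, `sigma_ratio`,
#'   standard error of the mean, and a chi-square statistic comparing the
#'   bin-to-bin scatter with binomial counting noise.
#' @export
verify_2d <- function(c11, system, c22_max = NULL, n_bins_2d = 20L,
                      cfg = sampler_config(1e6), wall_check = TRUE) {
  stopifnot(inherits(system, "system_spec"), system$D == 2L)
  th <- c(c1 = 4 * system$d1^2 / system$N, c2 = 4 * system$d2^2)
  if (c11 <= th[["c1"]] || c11 > th[["c2"]])
    stop("c11 must lie in (c1, c2]")
  if (is.null(c22_max)) c22_max <- th[["c2"]]
  N <- system$N
  c12_max <- sqrt(c11 * c22_max)
  nb <- as.integer(n_bins_2d)
  e12 <- seq(-c12_max, c12_max, length.out = nb + 1L)
  e22 <- seq(0, c22_max, length.out = nb + 1L)
  w12 <- 2 * c12_max / nb
  w22 <- c22_max / nb
  H0 <- matrix(0, nb, nb)
  H1 <- matrix(0, nb, nb)
  set.seed(cfg$seed)
  left <- cfg$n_cfg
  r1 <- sqrt(N * c11)
  r2max <- sqrt(N * c22_max)
  while (left > 0) {
    m <- as.integer(min(cfg$batch_size, left))
    left <- left - m
    Z1 <- matrix(stats::rnorm(m * N), m, N)
    X1 <- Z1 * (r1 / sqrt(rowSums(Z1^2)))
    Z2 <- matrix(stats::rnorm(m * N), m, N)
    rad2 <- r2max * stats::runif(m)^(1 / N)
    X2 <- Z2 * (rad2 / sqrt(rowSums(Z2^2)))
    c12 <- rowSums(X1 * X2) / N
    c22 <- rad2^2 / N
    i12 <- pmin(pmax(floor((c12 + c12_max) / w12) + 1L, 1L), nb)
    i22 <- pmin(pmax(floor(c22 / w22) + 1L, 1L), nb)
    idx <- (i22 - 1L) * nb + i12
    H0 <- H0 + matrix(tabulate(idx, nbins = nb * nb), nb, nb)
    ok <- if (wall_check) {
      Y <- matrix(stats::runif(m * N, system$d1, system$d2), m, N)
      rowSums(abs(X1) > 2 * Y) == 0L
    } else rep(TRUE, m)
    H1 <- H1 + matrix(tabulate(idx[ok], nbins = nb * nb), nb, nb)
  }
  mask <- admissible_mask(c11, c22_max, e12, e22)
  ratio <- ifelse(H0 > 0, H1 / H0, NA_real_)
  use <- mask & H0 > 0
  vals <- ratio[use]
  n0 <- H0[use]
  mean_ratio <- mean(vals)
  sigma_ratio <- stats::sd(vals)
  # binomial-consistency chi-square against the pooled (count-weighted)
  # common-W estimate under the factorization hypothesis
  w_pool <- sum(H1[use]) / sum(n0)
  v0 <- w_pool * (1 - w_pool)
  chisq <- sum((vals - w_pool)^2 * n0 / v0)
  dof <- length(vals) - 1L
  structure(list(
    c11 = c11, c22_max = c22_max, c12_max = c12_max,
    c12_edges = e12, c22_edges = e22,
    c12_centers = (e12[-1L] + e12[-length(e12)]) / 2,
    c22_centers = (e22[-1L] + e22[-length(e22)]) / 2,
    ratio = ratio, n_free = H0, n_wall = H1, mask = mask,
    mean_ratio = mean_ratio, sigma_ratio = sigma_ratio,
    se_mean = sigma_ratio / sqrt(length(vals)),
    chisq = chisq, chisq_dof = dof,
    chisq_p = stats::pchisq(chisq, dof, lower.tail = FALSE),
    system = system, n_cfg = cfg$n_cfg, seed = cfg$seed,
    wall_check = wall_check
  ), class = "verify2d_grid")
}

#' @export
print.verify2d_grid <- function(x, ...) {
  cat(sprintf(
    "D=2 factorization check: N = %d, lambda = %g, c11 = %g (n_cfg = %g)\n",
    x$system$N, x$system$lambda, x$c11, x$n_cfg))
  cat(sprintf("  <G/G0> = %.4f  sigma = %.4f  over %d admissible bins\n",
              x$mean_ratio, x$sigma_ratio, sum(x$mask & x$n_free > 0)))
  cat(sprintf("  chi-square vs counting noise: %.1f on %d dof (p = %.3f)\n",
              x$chisq, x$chisq_dof, x$chisq_p))
  invisible(x)
}

#' Write a verification grid as CSV plus JSON sidecar
#'
#' Long-format CSV (`c12_center, c22_center, ratio, n, admissible`) and a
#' JSON sidecar (`<path>.json`) with the summary statistics and
#' provenance.
#'
#' @param grid a [verify_2d()] result.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_verify2d <- function(grid, path) {
  df <- data.frame(
    c12_center = rep(grid$c12_centers, times = length(grid$c22_centers)),
    c22_center = rep(grid$c22_centers, each = length(grid$c12_centers)),
    ratio = as.vector(grid$ratio),
    n = as.vector(grid$n_free),
    admissible = as.vector(grid$mask))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(c11 = grid$c11, c22_max = grid$c22_max,
               mean_ratio = grid$mean_ratio, sigma_ratio = grid$sigma_ratio,
               se_mean = grid$se_mean, chisq = grid$chisq,
               chisq_dof = grid$chisq_dof, n_cfg = grid$n_cfg,
               seed = grid$seed,
               system = list(N = grid$system$N, D = grid$system$D,
                             d1 = grid$system$d1, d2 = grid$system$d2))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
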