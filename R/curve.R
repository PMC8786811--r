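#' Partition-coefficient curve container
#'
#' A `partition_curve` is a data.frame with one row per conformation bin and
#' columns `c` (bin center, length^2), `u` (normalized coordinate), `W`
#' (partition-coefficient estimate), `SE` (standard error, 0 for
#' deterministic oracles), `n_accepted`, `n_total` (per-bin counts, `NA`
#' for oracles), plus provenance attributes: the [system_spec()], the
#' estimator tag, the RNG seed, and whether `W` is absolutely normalized
#' (`absolute = FALSE` marks curves known only up to a constant factor,
#' e.g. Wang-Landau output).
#'
#' @param c,u,W,SE,n_accepted,n_total column vectors (recycled where scalar).
#' @param system a [system_spec()].
#' @param estimator character tag (e.g. `"oracle"`, `"direct"`, `"shell"`,
#'   `"wang-landau"`).
#' @param seed integer RNG seed used (NA for deterministic curves).
#' @param absolute logical; is `W` absolutely normalized?
#' @param extra named list merged into the metadata.
#' @return Object of class `c("partition_curve", "data.frame")`.
#' @export
partition_curve <- function(c, u, W, SE = 0, n_accepted = NA_real_,
                            n_total = NA_real_, system, estimator = "oracle",
                            seed = NA_integer_, absolute = TRUE,
                            extra = list()) {
  df <- data.frame(c = c, u = u, W = W, SE = SE,
                   n_accepted = n_accepted, n_total = n_total)
  attr(df, "system") <- system
  attr(df, "estimator") <- estimator
  attr(df, "seed") <- seed
  attr(df, "absolute") <- absolute
  attr(df, "extra") <- extra
  class(df) <- c("partition_curve", "data.frame")
  validate_partition_curve(df)
  df
}

#' Validate a partition curve
#'
#' Checks the structural invariants: required columns present, `u` strictly
#' increasing, `W >= 0`, `SE >= 0`, and (for absolutely normalized curves)
#' `W <= 1 + 3 SE`.
#'
#' @param curve a [partition_curve()].
#' @return The curve, invisibly; errors describe the violated invariant.
#' @export
validate_partition_curve <- function(curve) {
  need <- c("c", "u", "W", "SE", "n_accepted", "n_total")
  missing <- setdiff(need, names(curve))
  if (length(missing))
    stop("partition curve lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(curve) > 1 && any(diff(curve$u) <= 0))
    stop("u grid must be strictly increasing")
  if (any(curve$W < 0, na.rm = TRUE)) stop("W must be >= 0")
  if (any(curve$SE < 0, na.rm = TRUE)) stop("SE must be >= 0")
  if (isTRUE(attr(curve, "absolute")) &&
      any(curve$W > 1 + 3 * curve$SE + 1e-12, na.rm = TRUE))
    stop("absolute W exceeds 1 beyond 3 standard errors")
  invisible(curve)
}

#' @export
print.partition_curve <- function(x, ...) {
  sys <- attr(x, "system")
  cat(sprintf(
    "Partition curve (%s%s): %d bins, N = %d, D = %d, lambda = %g\n",
    attr(x, "estimator"),
    if (isTRUE(attr(x, "absolute"))) "" else ", relative normalization",
    nrow(x), sys$N, sys$D, sys$lambda))
  ok <- is.finite(x$W) & x$W > 0
  cat(sprintf("  u in [%.4g, %.4g]; W in [%.4g, %.4g]\n",
              min(x$u), max(x$u),
              if (any(ok)) min(x$W[ok]) else NA, max(x$W, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.partition_curve <- function(x, log_w = FALSE, ...) {
  y <- if (log_w) log(pmax(x$W, .Machine$double.xmin)) else x$W
  plot(x$u, y, xlab = "u", type = "b", pch = 16, cex = 0.5,
       ylab = if (log_w) "ln W" else "W", ...)
  invisible(x)
}

#' Evaluate the deterministic oracle on a grid as a partition curve
#'
#' Convenience wrapper building a [partition_curve()] from [w_exact_n1()]
#' (N = 1) or [w_quadrature()] (N = 2, 3) on a grid of `c` values.
#'
#' @param system a [system_spec()] with D = 1 and N in 1..3.
#' @param c_grid strictly increasing conformation values.
#' @param ... passed to [w_quadrature()].
#' @return A [partition_curve()] with `SE = 0`, estimator `"oracle"`.
#' @export
oracle_curve <- function(system, c_grid, ...) {
  stopifnot(system$D == 1L)
  W <- if (system$N == 1L) {
    w_exact_n1(c_grid, system$d1, system$d2)
  } else {
    vapply(c_grid, w_quadrature, numeric(1), system = system, ...)
  }
  partition_curve(c = c_grid, u = normalized_u(c_grid, system), W = W,
                  SE = 0, system = system, estimator = "oracle",
                  absolute = TRUE)
}

#' Write / read a partition curve as annotated CSV
#'
#' The on-disk format is a plain CSV with the six curve columns, preceded
#' by `#`-prefixed header lines carrying the provenance metadata
#' (system, estimator, seed, absolute flag). `read_curve(write_curve(x))`
#' is the identity on all fields and metadata.
#'
#' @param curve a [partition_curve()].
#' @param path file path.
#' @return `write_curve`: the path, invisibly. `read_curve`: the curve.
#' @export
write_curve <- function(curve, path) {
  validate_partition_curve(curve)
  sys <- attr(curve, "system")
  hdr <- c(
    sprintf("# wallconf partition curve v1"),
    sprintf("# N: %d", sys$N), sprintf("# D: %d", sys$D),
    sprintf("# d1: %.17g", sys$d1), sprintf("# d2: %.17g", sys$d2),
    sprintf("# estimator: %s", attr(curve, "estimator")),
    sprintf("# seed: %s", as.character(attr(curve, "seed"))),
    sprintf("# absolute: %s", as.character(isTRUE(attr(curve, "absolute")))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(curve)[, c("c", "u", "W", "SE",
                                            "n_accepted", "n_total")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", hdr[-1L])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  names(vals) <- keys
  for (k in c("N", "D", "d1", "d2", "estimator", "seed", "absolute"))
    if (!k %in% keys) stop("curve file header lacks field '", k, "'")
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("c", "u", "W", "SE", "n_accepted", "n_total")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("curve file lacks column(s): ", paste(missing, collapse = ", "))
  sys <- system_spec(as.integer(vals[["N"]]), as.numeric(vals[["d1"]]),
                     as.numeric(vals[["d2"]]), D = as.integer(vals[["D"]]))
  partition_curve(df$c, df$u, df$W, df$SE, df$n_accepted, df$n_total,
                  system = sys, estimator = vals[["estimator"]],
                  seed = suppressWarnings(as.integer(vals[["seed"]])),
                  absolute = identical(vals[["absolute"]], "TRUE"))
}
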