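#' Specify a confined dumbbell system
#'
#' Defines the geometry of `N` dumbbells in `D` dimensions whose
#' centers-of-mass are restricted to a slab `[d1, d2]` of distances from a
#' hard flat wall (wall normal along direction 1). All lengths are measured
#' in the same unit; the canonical choice is units of `d2` (so `d2 = 1`),
#' which the scaling relation makes fully general.
#'
#' @param N integer, number of dumbbells (>= 1).
#' @param d1 inner slab boundary (length, >= 0).
#' @param d2 outer slab boundary (length, > d1).
#' @param D integer, spatial dimension (>= 1), default 1.
#'
#' @return An object of class `"system_spec"`: a list with fields `N`, `D`,
#'   `d1`, `d2`, `lambda = d1/d2`, and `K = D*(D+1)/2`, the number of
#'   independent conformation-tensor constraints.
#' @examples
#' sys <- system_spec(N = 10, d1 = 0.8, d2 = 1)
#' thresholds(sys)
#' @export
system_spec <- function(N, d1, d2, D = 1L) {
  N <- as.integer(N)
  D <- as.integer(D)
  stopifnot(length(N) == 1L, length(D) == 1L, length(d1) == 1L, length(d2) == 1L)
  if (N < 1L) stop("N must be >= 1")
  if (D < 1L) stop("D must be >= 1")
  if (!(d1 >= 0 && d1 < d2)) stop("need 0 <= d1 < d2")
  structure(list(
    N = N, D = D, d1 = as.numeric(d1), d2 = as.numeric(d2),
    lambda = d1 / d2, K = D * (D + 1L) %/% 2L
  ), class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf(
    "Dumbbell system: N = %d, D = %d, slab [d1, d2] = [%g, %g] (lambda = %g)\n",
    x$N, x$D, x$d1, x$d2, x$lambda))
  th <- thresholds(x)
  cat(sprintf("  confinement thresholds: c1 = %g, c2 = %g (length^2)\n",
              th[["c1"]], th[["c2"]]))
  invisible(x)
}

#' Confinement thresholds c1 and c2
#'
#' Below `c1 = 4 d1^2 / N` no dumbbell can reach the wall and the partition
#' coefficient is exactly 1; above `c2 = 4 d2^2` no admissible configuration
#' exists and it is exactly 0. Between the two, confinement acts gradually.
#'
#' @param system a [system_spec()].
#' @return Named numeric vector `c(c1 = ..., c2 = ...)` in length^2 units.
#' @export
thresholds <- function(system) {
  stopifnot(inherits(system, "system_spec"))
  c(c1 = 4 * system$d1^2 / system$N, c2 = 4 * system$d2^2)
}

#' Normalized conformation coordinate u
#'
#' Maps the wall-normal conformation-tensor component `c` onto
#' `u = (c - c1) / (c2 - c1)`, so the confinement transition occupies
#' `u` in \[0, 1\]. Values outside \[0, 1\] are permitted (the input lies
#' outside the transition window) and returned as-is.
#'
#' @param c conformation value(s), length^2, >= 0.
#' @param system a [system_spec()].
#' @return Dimensionless numeric vector of the same length as `c`.
#' @export
normalized_u <- function(c, system) {
  th <- thresholds(system)
  if (th[["c2"]] <= th[["c1"]]) stop("degenerate system: c2 <= c1")
  (c - th[["c1"]]) / (th[["c2"]] - th[["c1"]])
}

#' Bead configuration of N dumbbells
#'
#' Holds the connector-vector components `X` (a `D x N` matrix, row `i`
#' being the i-th Cartesian component of all `N` connectors) and the
#' wall-normal center-of-mass coordinates `Y` (length-`N` vector with
#' `d1 <= Y <= d2`). A configuration is admissible w.r.t. the wall iff
#' `|X[1, mu]| <= 2 * Y[mu]` for every dumbbell `mu`.
#'
#' @param X numeric `D x N` matrix (a vector is taken as `1 x N`).
#' @param Y numeric length-`N` vector.
#' @param system a [system_spec()].
#' @return Object of class `"bead_configuration"` with fields `X`, `Y`,
#'   `admissible` (logical).
#' @export
bead_configuration <- function(X, Y, system) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  stopifnot(is.matrix(X), nrow(X) == system$D, ncol(X) == system$N,
            length(Y) == system$N)
  if (any(Y < system$d1 - 1e-12) || any(Y > system$d2 + 1e-12))
    stop("Y coordinates must lie in [d1, d2]")
  structure(list(
    X = X, Y = as.numeric(Y),
    admissible = all(abs(X[1L, ]) <= 2 * Y)
  ), class = "bead_configuration")
}

#' Instantaneous conformation tensor
#'
#' The second-moment tensor of the connector vectors,
#' `c_ij = (1/N) * sum_mu X[i, mu] * X[j, mu]`; symmetric and positive
#' semidefinite by construction.
#'
#' @param config a [bead_configuration()], or a bare `D x N` matrix `X`.
#' @param system a [system_spec()].
#' @return `D x D` symmetric matrix (a 1x1 matrix for D = 1).
#' @export
instantaneous_conformation <- function(config, system) {
  X <- if (inherits(config, "bead_configuration")) config$X else config
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) != system$D || ncol(X) != system$N)
    stop("X must be a D x N matrix")
  tcrossprod(X) / system$N
}

#' Rescale a conformation tensor and system by per-axis factors
#'
#' Applies the anisotropic scaling `c_ij -> c_ij / (s_i s_j)`,
#' `d -> d / s_1`, under which the partition coefficient is invariant.
#' For `D = 1` the normalized coordinate `u` is invariant as well.
#'
#' @param c conformation tensor (`D x D` matrix, or scalar for D = 1).
#' @param system a [system_spec()].
#' @param s numeric vector of `D` positive scale factors.
#' @return List with elements `c` (rescaled tensor, scalar if D = 1) and
#'   `system` (rescaled [system_spec()]).
#' @export
rescale <- function(c, system, s) {
  stopifnot(length(s) == system$D)
  if (any(s <= 0)) stop("scale factors must be positive")
  cm <- as_conformation_matrix(c, system$D)
  ct <- cm / tcrossprod(s)
  out_sys <- system_spec(system$N, system$d1 / s[1L], system$d2 / s[1L],
                         D = system$D)
  list(c = if (system$D == 1L) ct[1L, 1L] else ct, system = out_sys)
}

# Coerce a scalar / matrix to a validated symmetric PSD D x D matrix.
as_conformation_matrix <- function(c, D, tol = 1e-8) {
  cm <- if (is.matrix(c)) c else matrix(c, D, D)
  if (!is.matrix(cm) || nrow(cm) != D || ncol(cm) != D)
    stop("conformation tensor must be a D x D matrix")
  if (max(abs(cm - t(cm))) > tol * max(1, max(abs(cm))))
    stop("conformation tensor must be symmetric")
  ev <- eigen((cm + t(cm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop("conformation tensor must be positive semidefinite")
  cm
}
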