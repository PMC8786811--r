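# shared fixtures: canonical systems and exact N = 1 bin averages

sys_n1 <- system_spec(1, 0, 1)
sys_n2_l0 <- system_spec(2, 0, 1)
sys_n2_l08 <- system_spec(2, 0.8, 1)
sys_n3_l0 <- system_spec(3, 0, 1)
sys_n3_l08 <- system_spec(3, 0.8, 1)

# exact integral of the N = 1 density of states G(c) = c^(-1/2) (d2 - max(d1,
# sqrt(c)/2)) over [a, b] (a, b <= 4 d2^2), and of G0 = (d2 - d1) c^(-1/2)
n1_bin_G <- function(a, b, d1, d2) {
  cstar <- 4 * d1^2
  piece_lo <- function(lo, hi) (d2 - d1) * 2 * (sqrt(hi) - sqrt(lo))
  piece_hi <- function(lo, hi) 2 * d2 * (sqrt(hi) - sqrt(lo)) - (hi - lo) / 2
  lo1 <- a; hi1 <- min(b, cstar)
  lo2 <- max(a, cstar); hi2 <- b
  (if (hi1 > lo1) piece_lo(lo1, hi1) else 0) +
    (if (hi2 > lo2) piece_hi(lo2, hi2) else 0)
}

n1_bin_W <- function(a, b, d1, d2) {
  n1_bin_G(a, b, d1, d2) / ((d2 - d1) * 2 * (sqrt(b) - sqrt(a)))
}

# vectorized over equal-width bin edges
n1_bin_W_curve <- function(edges, d1, d2) {
  vapply(seq_len(length(edges) - 1L),
         function(i) n1_bin_W(edges[i], edges[i + 1L], d1, d2), numeric(1))
}

w_quad_vec <- function(cs, system, ...) {
  vapply(cs, w_quadrature, numeric(1), system = system, ...)
}
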