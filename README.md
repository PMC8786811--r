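# wallconf

Statistical mechanics of coarse-grained polymer molecules next to a hard
flat wall, resolved by their conformation tensor.

A polymer liquid flowing near a surface loses conformational freedom: the
wall forbids configurations that would cross it, and the closer a volume
element sits to the wall the fewer microstates its molecules retain. In
conformation-tensor viscoelastic modelling this loss must enter the
configurational entropy, because entropy gradients with respect to the
conformation tensor **c** are the driving forces for structural
relaxation. `wallconf` is for people building or validating such models:
it computes, for *N* dumbbell molecules in *D* dimensions whose centers of
mass lie in a slab `[d1, d2]` from the wall,

* the **partition coefficient** `W(c) = G(c)/G0(c)` — the confined to
  unconfined partition-function ratio at fixed conformation tensor, with
  `G0 = (d2−d1)^N det(c)^((N−D−1)/2)`, and
* the **configurational entropy change** `ΔS_c = k_B ln W`.

For `D = 1`, `W` equals 1 below `c1 = 4 d1²/N`, 0 above `c2 = 4 d2²`, and
in between follows the limit laws

```
1 − W ≃ a u^α,   α = (N+1)/2      (u → 0, requires d1 > 0)
    W ≃ b (1−u)^β,  β = 2N−1 = 4α−3  (u → 1)
```

with `u = (c − c1)/(c2 − c1)`. For `D > 1` the wall acts only through the
wall-normal component: `G(c) = W(c11) · G0(c)`.

The package provides closed forms and limit laws, deterministic quadrature
oracles (N ≤ 3), direct and shell Monte Carlo estimators, a Wang–Landau
flat-histogram sampler with the `t⁻¹` refinement schedule plus curve
merging, power-law and interpolating-function fitting, a YAML-config
experiment runner and a thin CLI (`inst/cli/wallconf.R`). The methods
vignette (`vignettes/confined-dumbbells.Rmd`) documents the model,
numerics and design choices.

## Worked example

Ten dumbbells in a near-wall slab with `λ = d1/d2 = 0.8`:

```r
library(wallconf)
sys <- system_spec(10, d1 = 0.8, d2 = 1)
sys
#> Dumbbell system: N = 10, D = 1, slab [d1, d2] = [0.8, 1] (lambda = 0.8)
#>   confinement thresholds: c1 = 0.256, c2 = 4 (length^2)
```

Below `c1 = 0.256` the molecules cannot feel the wall (`W = 1`); above
`c2 = 4` no configuration fits (`W = 0`, the forbidden sentinel `-Inf` in
entropy). A conformation with `W = 0.8998` costs
`entropy_change(0.8998) = -0.1056` (in units of `k_B`).

For two dumbbells the deterministic oracle and the shell Monte Carlo
estimator agree to within the Monte Carlo error:

```r
sys2 <- system_spec(2, 0.8, 1)
w_quadrature(1.5, sys2)
#> [1] 0.8901556
sample_shell(sys2, c(1.4, 1.6, 1.8), n_per_point = 1e5, seed = 1)[, 1:4]
#>     c          u       W           SE
#> 1 1.4 0.04411765 0.95474 0.0006573548
#> 2 1.6 0.11764706 0.81707 0.0012225654
#> 3 1.8 0.19117647 0.64410 0.0015140515
```

The onset prefactor constant `γ_N` is estimated from deep limit windows
and converted to the normalized prefactor `ln a`; the onset exponent is
recovered by the window rule (`W` within `[0.99, 1]`, 90% of the window
above `c1`) plus a log–log fit:

```r
g2 <- estimate_gammas(2, sys2)
theoretical_prefactors(sys2, g2)$ln_a
#> [1] 1.659902
fit_onset(onset_oracle_pipeline(sys2))
#> onset power-law fit over 90 bins (u+/u- = 179.0000):
#>   alpha = 1.4951 +- 0.0006 (95% CI)
#>   ln a = 1.6252 +- 0.0029
#>   R^2 = 0.999997
```

`alpha = 1.4951` sits at the theoretical `(N+1)/2 = 1.5` up to the
curvature of the finite fitting window.

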