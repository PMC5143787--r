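# scpkaczmarz

Sparsity-constrained preconditioned Kaczmarz (SCP-Kaczmarz) reconstruction
for fluorescence molecular tomography (FMT), with a desk-scale
diffusion-approximation forward simulator so every claim about the solver is
testable end to end without external data.

## The problem

FMT reconstructs the fluorescent yield x = ημ_af at N interior nodes from M
boundary light measurements, M < N, through a linear forward model
φ_m = A x derived from two coupled diffusion equations (excitation and
emission) with a Robin boundary condition. The rows of A are strongly
correlated, so the classical Kaczmarz / ART row-action solver — attractive
because it touches one equation at a time and needs no bulky matrix
factorizations during iteration — converges slowly.

This package implements the SCP-Kaczmarz remedy:

1. **Precondition.** From the SVD A = U S Vᵀ, form
   W = (S Sᵀ + λI)^(−1/2) Uᵀ and B = W A. The rows of B are mutually
   orthogonal (B Bᵀ = I_M for λ = 0, full row rank), so sequential Kaczmarz
   projections no longer interfere: a consistent system is solved in a
   single sweep.
2. **Sweep.** x ← x + B_iᵀ (y_i − B_i x)/(B_i B_iᵀ) for i = 1…M, with
   y = W φ_m.
3. **Threshold.** Zero all entries below β·max(x), choosing β so the Hoyer
   sparseness (√N − ‖x‖₁/‖x‖₂)/(√N − 1) of the iterate is as close as
   possible to a user-set target ψ (estimated from the target-volume
   fraction). This enforces sparsity and nonnegativity at once.

Steps 2–3 repeat until an iteration cap or until the update norm falls
below a tolerance. The package also provides the classical Kaczmarz
baseline, the field's evaluation metrics (relative deviation, Dice,
localization error), a 2D finite-volume diffusion simulator with Born-type
sensitivity assembly, phantom and random-system generators, MatrixMarket/CSV
I/O, ggplot2 plotting, and a four-subcommand CLI.

Audience: researchers in diffuse optical / fluorescence tomography who want
a tested, minimal reference implementation of sparsity-matched thresholded
row-action solvers, and methods developers who need reproducible synthetic
FMT systems to benchmark against.

## Worked example

Simulate the two-target phantom (two radius-1 mm disks in a 20 mm × 20 mm
muscle-like domain, 32 × 32 grid, 5 sources, 124 boundary detectors,
noise-free data) and reconstruct it:

```r
library(scpkaczmarz)

scen <- make_scenario(two_target_config(noise_level = 0))
psi  <- wanted_sparsity_from_fraction(2 * pi / 400, length(scen$x_true))

fit <- scp_kaczmarz(scen$A, scen$phi_m,
                    solver_config(wanted_sparsity = psi, max_iterations = 100),
                    x_true = scen$x_true)
fit
#> <scpk_fit> method: scp_kaczmarz, 100 iteration(s), stopped at iteration cap
#>   final sparsity 0.9046, update norm 2.602e-03, relative deviation 0.2356

evaluate_reconstruction(fit$x, scen$x_true, scen$grid)
#> # A tibble: 1 × 5
#>   delta   dice dice_support sparsity localization_error_mm
#>   <dbl>  <dbl>        <dbl>    <dbl>                 <dbl>
#> 1 0.236 0.0390        0.875    0.905                0.0312
```

After 100 sweeps the reconstruction deviates from the truth by 24% in
ℓ₂ norm, overlaps 88% of the true support at the 10%-of-maximum isocontour,
sits within 0.03 mm of the true center of mass, and holds the requested
sparseness 0.90. The classical baseline on the same data is still at
δ ≈ 0.94 after 100 sweeps:

```r
glance(classical_kaczmarz(scen$A, scen$phi_m,
         solver_config(max_iterations = 100, apply_sparsity_constraint = FALSE),
         x_true = scen$x_true))["delta"]
#> # A tibble: 1 × 1
#>   delta
#>   <dbl>
#> 1 0.935
```

`tidy(fit)` returns the per-iteration trace (δ, Dice, sparsity, update
norm, β) as a tibble and `autoplot(fit)` plots it; `plot_yield(fit$x,
scen$grid)` images the reconstruction.

For noisy measured data, pass `truncate` (spectral cutoff near the
noise-to-signal ratio) to `scp_kaczmarz()` — see the methods vignette for
why diagonal loading alone cannot stop noise amplification inside row
projections.

## Command line

```sh
Rscript inst/cli/fmtrecon.R simulate    --config scenario.txt --seed 7 --out sim/
Rscript inst/cli/fmtrecon.R precondition --matrix sim/A.mtx --out pre/
Rscript inst/cli/fmtrecon.R reconstruct --method scp --matrix sim/A.mtx \
        --measurements sim/phi_m.csv --truth sim/x_true.csv --psi 0.9 --out rec/
Rscript inst/cli/fmtrecon.R evaluate    --recovered rec/x.csv \
        --truth sim/x_true.csv --config scenario.txt --out report.csv
```

Matrices travel as MatrixMarket `.mtx`, vectors as single-column CSV with a
self-describing header, scenarios as flat `key = value` files.

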