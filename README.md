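# chemosense

Cells climbing a chemoattractant gradient can sense it in two ways:
**temporally**, comparing receptor output at different points along their
path, or **spatially**, comparing output between their front and back
halves. chemosense is an R package for simulating that choice. It models a
cell as a one-dimensional ring of membrane compartments carrying a
three-node adaptive signaling circuit — negative integral feedback (NFB) or
an incoherent feedforward loop (IFF) — moving through a gradient, and asks
which sensing strategy accumulates the larger output. It is intended for
systems-biology modelers studying gradient sensing, network motifs and
local-excitation/global-inhibition (LEGI) mechanisms.

## The model

Both circuits couple an activator *A* (driven by the input *I*), an
inactivator *B*, and an output *C*:

    dA/dτ = k_IA I − l_FA A
    dB/dτ = k_CB C − l_FB          (NFB; zero-order decay, B clamped at 0)
    dB/dτ = k_IB I − l_FB B        (IFF)
    dC/dτ = k_AC A (1−C)/(K_AC+1−C) − l_BC B C/(L_BC+C)

Both adapt perfectly: the NFB steady-state output is exactly
`l_FB/k_CB`, and the IFF balance point is input-independent because *A*
and *B* scale together. On the ring, all three proteins diffuse and each
compartment sees the local input as the cell traverses the gradient.
Physics enters only through five dimensionless groups: the gradient group
`α = v k / l_BC`, the speed group `β = v/(d l_BC)`, and the diffusivities
`D'_X = D_X/(d² l_BC)`.

Sensing performance over a traversal is measured by

    O_T = (1/N) ∫ Σ_i (C_i(τ)/C_i(0) − 1) dτ      (temporal)
    O_S = ∫ (Σ_front C_i / Σ_back C_i − 1) dτ     (spatial)

and the strategy with the larger positive output wins (`O_TS = O_T/O_S`,
ties → temporal; both non-positive → sensing failure).

The package provides: log-uniform parameter screening by sensitivity and
adaptation precision (`screen_parameters`), the ring simulator with
stiff method-of-lines integration (`simulate_ring`), the output
functionals and decision (`sensing_outputs`), factorial sweeps over
`(β, D'_A, D'_B, α)` with decision-fraction summaries (`run_sweep`,
`fraction_favoring`), stochastic ensembles under external chemoattractant
noise and internal kinetic noise with viability criteria (`run_ensemble`),
and a small cell atlas applying the `β = v/(d l_BC)` criterion to real
cells (`beta_value`, `classify_cells`).

## Worked example

Screen IFF parameter sets, then simulate a slow LEGI-configured cell and a
fast cell through the same shallow linear gradient:

```r
library(chemosense)

sel <- screen_parameters(3000, "IFF", seed = 7, n_keep = 10)
sel
#> Adaptation screen (IFF): 3000 sampled, 107 passed (S >= 1, P >= 10), 10 kept

slow <- simulate_ring(sel$selected[[1]],
                      ring_transport(beta = 0.125, D_A = 1, D_B = 100),
                      gradient_profile("linear"))
slow
#> Ring-cell trajectory: IFF circuit, N = 20, beta = 0.125, D' = (1, 100, 0)
#>   linear profile, I_L = 0.5 -> I_H = 0.51, tau in [0, 30]
#>   O_T = 0.02105, O_S = 0.09895 -> spatial sensing

fast <- simulate_ring(sel$selected[[1]],
                      ring_transport(beta = 8, D_A = 1, D_B = 100),
                      gradient_profile("linear"))
sensing_outputs(fast)
#> O_T = 0.021026, O_S = 0.0016743, O_TS = 12.559 -> temporal sensing
```

The slow cell (`β = 0.125`) with a slow activator and fast inactivator
(`D'_A = 1 < D'_B = 100`) develops a strong front/back asymmetry — the
inactivator made at the front diffuses to the back and suppresses the
output there — so spatial sensing yields about five times the temporal
output. The fast cell (`β = 8`) outruns that coupling: the front/back
signal collapses (`O_S` drops sixty-fold) and temporal sensing wins.
`plot(slow)` shows the mean, front and back output series.

For a real cell, the same criterion needs only speed, diameter and a
signaling rate:

```r
beta_value(v = 20, d = 2, l_BC = 2.2)   # E. coli
#> [1] 4.545455  — rounds to 4.5: well above 1, temporal sensing
classify_cells(system.file("extdata", "cells_demo.csv", package = "chemosense"))
#>               name diameter_um speed_um_s l_bc_per_s motility_class     beta classification
#> 1 Escherichia coli           2         20        2.2      flagellar 4.545455       temporal
```

See the methods vignette (`vignettes/chemosense-methods.Rmd`) for the full
model description, parameter conventions, noise models and known
limitations.

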