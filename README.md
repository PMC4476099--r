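# embryosens

Global sensitivity analysis of a dynamic reaction–diffusion model of gene
expression in the early *Drosophila* embryo.

## The scientific problem

In the syncytial blastoderm, nuclei share a common cytoplasm, so both mRNA
and protein can diffuse between neighbouring nuclear territories while being
synthesized and degraded. A long-standing question is which process —
transcription or translation — contributes more to the variance in protein
levels. `embryosens` addresses this with a deterministic dynamic model and
quasi-Monte Carlo global sensitivity analysis, asking how much of the
variance in predicted protein output is attributable to each kinetic
parameter, alone and in pairwise interaction, and how those attributions
change over developmental time.

## The model

For a chain of *n* nuclei (default *n* = 52), let *y₁…yₙ* be mRNA and
*yₙ₊₁…y₂ₙ* protein concentrations. With transcription rate σ, mRNA diffusion
*d*, mRNA decay λ, translation τ, protein diffusion δ and protein decay γ
(all min⁻¹), interior nuclei obey

    dyᵢ/dt    = σ + d[(yᵢ₊₁ − yᵢ) + (yᵢ₋₁ − yᵢ)] − λ yᵢ
    dyₙ₊ᵢ/dt  = τ yᵢ + δ[(yₙ₊ᵢ₊₁ − yₙ₊ᵢ) + (yₙ₊ᵢ₋₁ − yₙ₊ᵢ)] − γ yₙ₊ᵢ

with zero-flux boundaries (the end nuclei exchange with their single
neighbour only). The system is integrated by classic fixed-step RK4
(compiled, batched over thousands of parameter sets at once).

Sensitivity is quantified by High Dimensional Model Representation (HDMR):
the scalar model output *f*(x) (protein at a chosen nucleus and time) is
decomposed over the unit hypercube as

    f(x) = f₀ + Σᵢ fᵢ(xᵢ) + Σᵢ<ⱼ fᵢⱼ(xᵢ, xⱼ) + …

with component functions expanded in orthonormal shifted-Legendre
polynomials and estimated by quasi-Monte Carlo projection over a Sobol
design. First-order indices Sᵢ = Var(fᵢ)/D and pairwise indices
Sᵢⱼ = Var(fᵢⱼ)/D measure each parameter's share of the output variance D.

## Worked example

Sensitivities of middle-nucleus protein at *t* = 4 min for a ubiquitously
expressed gene (initial mRNA and protein levels 1.0), over the calibrated
parameter hypercube:

```r
library(embryosens)
space  <- default_parameter_space()
design <- sobol_design(4096, space)
out <- evaluate_objective_batch(design, initial_condition("ubiquitous", 1),
                                "middle_nucleus", times = 4)
h <- hdmr_decompose(design, out[, "t4"])
print(h)
#> HDMR decomposition (N = 4096, degree 3)
#>   mean output f0 = 1.84, total variance D = 1.997
#>   first-order indices:
#> sigma     d   lam   tau delta gamma
#> 0.318 0.000 0.173 0.310 0.000 0.052
#>   sum S_i = 0.853, sum S_ij = 0.141

cmp <- compare_to_reference(h$first_order)
cat(sprintf("Pearson r vs measured contributions: %.3f (max |diff| %.3f)\n",
            cmp$pearson_r, cmp$max_abs_diff))
#> Pearson r vs measured contributions: 0.966 (max |diff| 0.088)
```

Transcription (σ) and translation (τ) dominate (≈ 0.32 each), mRNA decay
(λ) follows (≈ 0.17), protein decay (γ) is minor (≈ 0.05) and both
diffusion rates are irrelevant for a spatially uniform gene — a pattern
that correlates strongly (r > 0.96) with contribution-to-variance fractions
measured experimentally for mammalian housekeeping genes (transcription
0.38, mRNA decay 0.18, translation 0.30, protein decay 0.14). Re-running
the decomposition at later analysis times (`times = c(4, 10)`) shows the
sensitivity landscape is dynamic: λ overtakes τ by *t* = 10 min.

`run_sensitivity_grid()` automates the full factorial analysis — five
initial conditions × four spatial objectives × eleven time points — and
`sensitivity_time_series()` reshapes any slice of it into figure-ready
per-parameter trajectories.

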