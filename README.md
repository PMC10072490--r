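# mitonetseg

Spatial simulation and analytic theory of how mitochondrial network
structure shapes the inheritance of mitochondrial DNA (mtDNA) at cell
division.

## The problem

A dividing cell partitions its $N_0$ mtDNA molecules — a fraction $h$ of
them mutant (the *heteroplasmy*) — between two daughters. The
cell-to-cell variance of daughter heteroplasmy, conveniently normalised
as $V'(h) = V(h) / (h(1-h))$, drives the mitochondrial genetic
bottleneck; under the binomial null (every molecule independently
inherited with the cytoplasm fraction $p_c$) it is
$(1-p_c)/(p_c N_0)$, i.e. $1/N_0$ for symmetric division, and
$V(N) = N_0 p_c (1-p_c)$.

Real mtDNA is partly confined to the fused mitochondrial network, which
is inherited in spatially correlated chunks. `mitonetseg` simulates a
random network of total length $U^* = 50$ cell radii grown from $s$
perimeter seed points in a circular cell ($s$ tunes heterogeneity),
places wildtype and mutant molecules in the network with genotype-specific
inclusion probabilities $p$ and $q$ (optionally with a mutual-repulsion
halo $l$, optionally followed by fragmentation-and-diffusion of scale
$\lambda$), cuts out a random sector daughter of angle $\phi$, and
records inherited counts $W, M$, heteroplasmy, and network mass fraction
$u$. Alongside the simulator sit the matching analytic models, with the
inherited network fraction $U \sim \mathrm{Beta}(\alpha,\beta)$ fitted
by moments:

- binomial null (Eqs above);
- random placement: beta-binomial compounding, giving
  $V(N) = N_0 p_c(1-p_c) + \kappa N_0(\kappa N_0 - 1) V(U)$ with
  $\kappa = p(1-h)+qh$, and the first-order delta-method
  $V_1'(h) = \frac{1-p_c}{p_c N_0} + \frac{V(U)}{p_c^2}\big(h(1-h)(p-q)^2
  - (ph + q(1-h))/N_0\big)$;
- repulsive placement: hypergeometric filling of
  $\lfloor u \cdot S \rfloor$ exclusion slots (qualitative by design);
- exact routes: an exhaustive state-space moment sum (Gauss–Jacobi
  quadrature over $U$) and a brute-force enumeration oracle, plus a
  second-order delta method built from exact fourth-order joint moments.

The punchline reproduced by simulation and theory alike: genotype-*biased*
network inclusion ($p \ne q$) in a heterogeneous network inflates
heteroplasmy variance (maximally when the majority type is fully
networked), equal inclusion correlates the genotypes and keeps $V'(h)$
near the null while inflating $V(N)$, homogeneous networks plus mtDNA
self-avoidance push both variances *below* binomial, and pre-division
diffusion washes everything back to the null.

## Worked example

Heterogeneous networks ($s = 4$), all wildtype molecules networked and
all mutants cytoplasmic ($p = 1$, $q = 0$), symmetric division:

```r
library(mitonetseg)
set.seed(7)
ens <- run_ensemble(growth_params(s = 4),
                    genetic_params(100, h = 0.5, p = 1, q = 0),
                    n_reps = 2000)
ens
#> Division ensemble: 2000 replicates (2000 with N > 0)
#>   mother: N0 = 100, h = 0.5, p = 1, q = 0
#>   E(N) = 50.11, V(N) = 50.36
#>   E(h) = 0.5053, V(h) = 0.005669, V'(h) = 0.02268
#>   E(U) = 0.5022, V(U) = 0.01167
```

The simulated $V'(h) = 0.0227$ is more than double the binomial-null
$1/N_0 = 0.01$: the variable inherited network fraction
($V(U) = 0.0117$ for these lopsided $s = 4$ networks) feeds straight
into heteroplasmy variance because only one genotype rides the network.
Fitting the beta model to the observed $(E(U), V(U))$ and evaluating
the theory at the same parameters:

```r
bp <- fit_beta(ens$summary$E_U, ens$summary$V_U)   # alpha = 10.25, beta = 10.16
exact_moments_sum(model_spec(100, 0.5, 1, 0, u_dist = bp),
                  check_convergence = FALSE)
#> Inheritance prediction [exact_sum]
#>   E(N) = 50.1107, V(N) = 53.5982
#>   E(h) = 0.504934, V(h) = 0.00584128, V'(h) = 0.0233651
```

Theory and simulation agree within Monte-Carlo error ($V(N)$: 50.4
simulated vs 53.6 at the fitted $V(U)$, within the spread of the
variance estimator at 2000 replicates; $V'(h)$: 0.0227 vs 0.0234). The
closed forms give the same numbers as the exact sum's first-order
counterpart (`closed_form_copy_number`: 53.6;
`closed_form_heteroplasmy`: 0.0214, the first-order truncation sitting
slightly below the exact 0.0234).

A command-line interface wraps the same functionality
(`inst/cli/mitonet.R`): subcommands `simulate`, `analytic`, `sweep`,
`fixtures`, with flags/config file, deterministic seeding, and JSON
manifests next to every output.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the diffusion-scale
calibration `t3`: the RMS net displacement (in units of $\lambda$) of
molecules after the model's 100-step pre-division diffusion, measured on
10,000 unconfined walks, and writes it as JSON.

## Layout

- `R/` — network growth, population placement/diffusion, division and
  ensembles, analytic models (closed forms, delta methods, exact sum,
  enumeration oracle), sweeps, CLI.
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (end-to-end scientific checks).
- `vignettes/network-partitioning.Rmd` — the model, its assumptions,
  numerical choices, and known limitations.
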