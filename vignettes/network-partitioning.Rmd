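---
title: "Mitochondrial networks and mtDNA partitioning noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial networks and mtDNA partitioning noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(mitonetseg)
```

## The problem

When a cell divides, its mitochondrial DNA (mtDNA) molecules are
partitioned between the daughters. If a fraction $h$ of the mother's
$N_0$ molecules carry a mutation (the *heteroplasmy*), the daughters'
heteroplasmies spread around $h$; this cell-to-cell variance is the
engine of the mitochondrial *genetic bottleneck*, which lets cell lineages
segregate mutant load. The null expectation is binomial: every molecule
independently inherited with the cytoplasm fraction $p_c$, giving
normalised heteroplasmy variance

$$V'(h) = \frac{V(h)}{h(1-h)} = \frac{1-p_c}{p_c N_0},$$

i.e. $1/N_0$ for symmetric division. But mtDNA is not free-floating: a
fraction of it resides in the fused mitochondrial *network*, whose spatial
arrangement is inherited in correlated chunks. This package asks, by
simulation and by matching analytic models, how network structure,
genotype-biased network inclusion, mtDNA self-avoidance, and pre-division
diffusion move the copy-number variance $V(N)$ and heteroplasmy variance
$V'(h)$ above or below the binomial null.

## The spatial simulator

**Cell and network.** The cell is the unit disc (all lengths in units of
the cell radius $r$). A network is grown from $s$ evenly spaced perimeter
seed points (common random rotation) by elongation and branching: each
active tip advances $e = 0.01$ per time step and branches with Poissonian
rate $k = 0.02$ per step; tips are clipped and killed at the boundary;
if all tips die the perimeter is re-seeded. Growth stops when the total
length reaches $U^* = 50$ (the final increment is trimmed so the mass is
exact). With $r = 40\,\mu m$ and tubule width $0.4\,\mu m$ this is
$\sim 16\%$ of the cell area, a realistic mitochondrial content. The
seed count $s$ is the heterogeneity dial: $s = 4$ gives lopsided,
heterogeneous networks, $s = 64$ near-homogeneous ones.

Choices the growth description leaves open, fixed here once:

* *Time discretisation*: unit steps; branch probability $1 - e^{-k}$ per
  tip per step.
* *Branch geometry*: a branch spawns a new tip at the parent's position
  with direction deviated uniformly within $\pm\pi/2$ of the parent's;
  the parent continues unchanged; tips never turn, so every tip traces a
  straight chord. No fusion of tips.
* *Sector masses* are computed by subdividing segments to resolution $e$
  and classifying midpoints by polar angle (error $O(e)$ per sector
  boundary crossing); exact polyline clipping against two radii is
  error-prone near the centre and not worth it at this resolution.

**Population.** Of the $(1-h)N_0$ wildtype molecules a proportion $p$ is
placed on the network, and of the $hN_0$ mutants a proportion $q$
(fractional counts rounded half away from zero, complements by
subtraction, so totals are conserved exactly). Networked molecules are
placed uniformly by arc length; the rest uniformly by area in the disc.
Two optional physical effects:

* *Self-avoidance* (`placement_params("repulsive", l)`): networked
  molecules are placed in a single shuffled genotype order (so neither
  genotype systematically wins contested space), and a candidate closer
  than $l$ (Euclidean) to an already placed networked molecule is
  redrawn, up to 1000 attempts, after which the best candidate seen is
  accepted and a relaxation event logged. $l = 0.05$ is a $2\,\mu m$
  spacing in a $40\,\mu m$ cell, within observed inter-nucleoid
  distances.
* *Pre-division diffusion* (`diffusion_params(lambda)`): the network
  fragments and every molecule takes 100 isotropic Gaussian steps of RMS
  length $\lambda$ (per-axis s.d. $\lambda/\sqrt 2$), so an unconfined
  walk nets $10\lambda$ RMS. Steps that would exit the disc are
  resampled (100 tries, then the molecule stays put for that step).

**Division.** A sector of angle $\phi$ at uniform orientation is the
daughter; it inherits the molecules inside it, a fraction $u$ of the
network mass, and $p_c = \phi/360$ of the area in expectation. Ensembles
(`run_ensemble`) regrow the network per replicate by default; a fixed
network or a pre-grown pool can be supplied for variance decomposition
or to amortise growth cost. Heteroplasmy moments are taken over
replicates with $N > 0$ (reported as `n_defined`); variances use the
unbiased estimator.

## The analytic models

Write $W_n, W_c, M_n, M_c$ for the daughter's wildtype/mutant counts in
network/cytoplasm, $w_n = p(1-h)N_0$ etc. for the mother's compartment
counts, and $U$ for the inherited network mass fraction, modelled as
$\mathrm{Beta}(\alpha, \beta)$ with mean $p_c$ and variance $V(U)$
fitted to the simulated networks (`fit_beta` moment matching).

* **Null** ($p = q = 0$): $W \sim \mathrm{Bin}((1-h)N_0, p_c)$,
  $M \sim \mathrm{Bin}(hN_0, p_c)$, so $V(N) = N_0 p_c(1-p_c)$ and, to
  first order, $V'(h) = (1-p_c)/(p_c N_0)$.
* **Random placement**: conditional on $U = u$, networked counts are
  $\mathrm{Bin}(w_n, u)$ and $\mathrm{Bin}(m_n, u)$ — beta-binomial
  marginally, with the shared $U$ coupling the genotypes:
  $\mathrm{Cov}(W_n, M_n) = w_n m_n V(U)$. Total-variance assembly gives
  $$V(N) = N_0 p_c (1 - p_c) + \kappa N_0 (\kappa N_0 - 1) V(U), \qquad
  \kappa = p(1-h) + qh,$$
  and the first-order delta method gives
  $$V_1'(h) = \frac{1-p_c}{p_c N_0} + \frac{V(U)}{p_c^2}
  \Big( h(1-h)(p-q)^2 - \frac{ph + q(1-h)}{N_0} \Big).$$
  The $(p-q)^2$ term is the headline: genotype-biased network inclusion
  inflates heteroplasmy variance in proportion to the inherited-network
  variability, maximally when the majority type is fully networked and
  the minority fully cytoplasmic.
* **Repulsive placement**: the inherited network offers
  $d(u) = \min(\lfloor u \cdot S\rfloor, w_n + m_n)$ exclusion slots,
  filled without replacement:
  $W_n \mid u \sim \mathrm{Hypergeometric}(w_n + m_n, w_n, d(u))$ and
  $M_n = d(u) - W_n$, so the genotypes anti-correlate
  ($\mathrm{Cov} = -V(W_n \mid u)$). The slot total $S$ is exposed with
  two presets: `literal` ($\lfloor 1/l\rfloor$, slots per unit length as
  the $\lfloor u/l \rfloor$ draw count reads) and `geometric`
  ($\lfloor U^*/l\rfloor$, slots along the whole network, the default —
  the literal preset offers fewer slots than molecules at typical
  parameters). This model is qualitative by construction: it imposes
  even spreading more strictly than the simulator can.

Besides closed forms and the first-order delta method, two heavier
routes are implemented: an **exhaustive moment sum** over the state
space (conditional independence given $U$ reduces the four-fold sum to
two discrete convolutions and a 2-D grid per quadrature node; the
$(W, M) = (0,0)$ atom is excluded from $h$-moments and its mass
reported) and a **brute-force enumeration** oracle (every state tuple,
no shortcuts, $N_0 \le 12$) against which the sum is tested. A
**second-order** delta method (generic multivariate form, using exact
joint central moments to order four) is validated only against the
exhaustive sum, never assumed term-perfect: it contributes a
compensatory correction on the $p = q$ diagonal but the expansion
converges slowly whenever spatial structure correlates the genotypes.

## Numerical choices

* **Quadrature.** Integrals against the Beta law use Gauss–Jacobi rules
  that absorb the Beta weight exactly (Golub–Welsch on the Jacobi
  recurrence). A plain Legendre rule weighted by the density was
  rejected: beta shapes fitted at asymmetric division can fall below 1,
  making the density singular at 0 and the unweighted rule badly
  inaccurate, while the Jacobi rule reproduces Beta moments to machine
  precision for all feasible shapes. Default 200 nodes with optional
  node-doubling convergence check (warning at relative change
  $> 10^{-8}$).
* **Exact mass trimming** of the final growth increments makes
  `total_mass == mass_target` an exact invariant rather than an
  $O(e \cdot \#tips)$ overshoot.
* **Boundary handling under diffusion** resamples offending steps. This
  kernel is not symmetric near the boundary, so its stationary law is
  slightly centre-biased ($E\|x\|^2 \approx 0.43$ at $\lambda = 0.5$
  instead of $1/2$); area-uniformity is approached only as $\lambda$
  grows. Partitioning statistics are unaffected: the angular law — all
  that a random sector sees — is exactly uniform by symmetry.
* **Child seeds** for sweep cells come from a small multiplicative hash
  of (master seed, cell index), kept below $2^{31}$; identical
  configuration and master seed reproduce every cell exactly.

## What the generator emulates, and what a green test establishes

The growth process is a *structure generator*, not a biophysical model:
it produces a tunable family of network morphologies (heterogeneous to
homogeneous) of fixed total mass, which is all the inheritance models
consume. Its defaults are the stated world of the analyses here:
$e = 0.01$, $k = 0.02$, $U^* = 50$, $s \in \{4, 16, 64\}$,
$N_0 \in \{100, 1000\}$, $h \in \{0.1, 0.5\}$, $p_c \in \{0.5, 0.1\}$,
$l \in \{0, 0.05, 0.1\}$. Real mitochondrial networks grow by fission
and fusion, are three-dimensional, exchange mtDNA with the cytoplasm
between divisions, and couple to the cell cycle; none of that is
modelled, so green tests establish internal consistency of simulator
and theory and the direction and rough magnitude of structural effects
— not quantitative predictions for any particular cell type.

Two known honest gaps between stated expectations and what the stated
world delivers, kept visible rather than patched:

* The first-order value $(1-p_c)/(p_c N_0)$ understates the true
  binomial-null $V'(h)$ (exact sum: $0.01031$ at $N_0 = 100$, $p_c =
  1/2$; $0.1026$ at $p_c = 0.1$). At $10^5$ replicates the Monte-Carlo
  error is smaller than this truncation bias, so a $3$-SE comparison of
  simulation against the first-order formula fails there while the same
  simulation matches the exact sum within noise. The figure baselines
  use the exact ("analytic sum") null for precisely this reason.
* The diffusion boundary rule's radial bias (above) means "area-uniform
  at $\lambda \ge 0.5$" holds only angularly; radial uniformity needs
  larger $\lambda$.

## Tunable parameters at a glance

| parameter | meaning | default | units |
|---|---|---|---|
| `s` | perimeter seed count (heterogeneity dial) | — | count |
| `e` | elongation per tip per step | 0.01 | cell radii |
| `k` | branch rate per tip per step | 0.02 | 1/step |
| `mass_target` | total network length $U^*$ | 50 | cell radii |
| `N0`, `h` | mother copy number, heteroplasmy | — | count, fraction |
| `p`, `q` | wildtype / mutant network inclusion | — | fraction |
| `phi` (`p_c`) | daughter sector angle (area fraction) | 180 (0.5) | degrees |
| `l` | exclusion halo radius | 0 | cell radii |
| `lambda` | RMS diffusion step length | 0 | cell radii |
| `n_steps` | diffusion steps | 100 | count |

## Known limitations

* One daughter per division is recorded (a diagnostic mode tracks both
  and checks conservation); daughter–daughter covariance and
  multi-generation lineages are out of scope.
* No mtDNA turnover, selection, replication or recombination between
  divisions; no spatially correlated genotype placement (clonal
  clustering), which would likely add further heteroplasmy variance.
* The repulsive statistical model is qualitative (see above); its
  variances are more extreme than simulation by construction.
* 2-D geometry; the parameters can be retuned but not the
  dimensionality.
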