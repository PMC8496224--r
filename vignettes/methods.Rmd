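---
title: "Mechanistic trait simulation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic trait simulation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnisim)
```

## The model and its assumptions

`omnisim` simulates a quantitative trait bottom-up. Its assumptions, in
order of consequence:

1. **Omnigenic architecture.** A small subset of *core* genes contributes
   to the trait directly (their protein products enter the trait sum);
   every other gene is *peripheral* and affects the trait only by
   regulating, directly or through the network, the core genes.
2. **Thermodynamic transcriptional control.** Each gene's mRNA production
   rate is proportional to the equilibrium binding probability of RNAP II
   at its promoter, modulated by the protein concentrations of its
   activators and repressors. Translation is not regulated: protein
   production is linear in mRNA.
3. **Mass-action kinetics with first-order decay** for both species, plus
   either multiplicative noise (stochastic mode) or a diffusion time delay
   (delay mode) — never both, since the delay solver cannot interpret a
   stochastic path and the stochastic problem is posed with zero delay.

The coupled equations per gene $i$:

$$\dot x_i = K_{x,i}\, p_i(s(t-\tau)) - Z_{x,i} x_i,\qquad
  \dot s_i = K_{s,i}\, x_i(t-\tau) - Z_{s,i} s_i.$$

The binding probability is assembled from per-regulator factors. For a
regulator $j$ of gene $i$ with protein concentration $s_j$:

* activator factor
  $\left[\frac{h_A + s_j^2 e^{-G_{A,j}}\Phi_j}{h_A + s_j^2 e^{-G_{A,j}}}\right]^{1/n_b}$
  — equals 1 at $s_j = 0$ and exceeds 1 iff $\Phi_j > 1$;
* repressor factor $\left[1 + h_R s_j^2 e^{-G_{R,j}}\right]^{-1/n_b}$ —
  in $(0, 1]$, strictly decreasing.

$F_i$ is the product of all masked factors (the determinant of the product
of the diagonal factor matrices), and

$$p_i = \frac{2}{1 + F_i^{-1} e^{G_{p,i}/H_i}}, \quad \text{clamped to } [0,1].$$

### Why this form of $p$

The source algebra for the binding probability admits two readings: the
*occupancy* form above, and a *literal* matrix reading
$p = 2(I+F)^{-1}e^{-G_p H^{-1}}\mathbf 1$. The literal reading makes a
stronger activator (larger $F$) *decrease* the binding probability, which
contradicts the expected sign structure of regulation (a target's
expression should correlate positively with its activator's). We adopt the
occupancy form as the default and keep the literal form available via
`regulatory_params(..., binding_form = "literal")`. The leading factor 2
allows raw values up to 2, so values are clamped to $[0,1]$; at the
default baseline ($F = 1$, $G_p/H = \log 3$) the probability is 0.5 with
no clamping active.

### The $1/n_b$ exponent

The factor exponents are written with $n_b$ equal to the number of genes in
the network, and that is the default (`exponent_base = n`). This makes each
individual regulator's leverage shrink as the network grows, which is the
stated convention; an alternative that uses each gene's own regulator count
(`exponent_mode = "regulators"`) is provided but not default.

## Parameters, units, defaults

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| `Gp` | RNAP II binding free energy | $H$ units | $\log 3$ | baseline $p = 0.5$ |
| `H` | RNAP II binding constant | — | 1 | scale of `Gp` |
| `GA`, `GR` | regulator binding energies | — | 0 | neutral binding |
| `Phi` | activator interaction constant | — | 2 | activation strength > 1 |
| `hA`, `hR` | activator/repressor constants | — | 1 | neutral scale |
| `P_mu` | mean expression rate | molecules/min | 10 | keeps the truncation of $P \sim N(P_\mu, \kappa P_\mu)$ negligible (CV$^2 = \kappa/P_\mu \le 0.1$) |
| `Ks` | translation rate | /min | 1 | mammalian order of magnitude |
| `Zx`, `Zs` | degradation rates | /min | 0.05 | ~14 min half-life; relaxation well inside default `Tmax` |
| `Tmax` | time span | min | 1000 | ≥ 50 relaxation times |
| `tau` | diffusion delay | min | 0 | off unless delay mode |
| `gamma`, `sigma_q` | noise amplitude, variance | — | 0, 0.1 | off unless stochastic mode |
| `burn_in` | discarded head fraction | — | 0.2 | first 20% of the run holds the initial-condition transient |

These kinetic defaults are repository choices at a mammalian-cell order of
magnitude; they are deliberately not presented as values from any external
source. All are configurable through `kinetic_params()` /
`regulatory_params()` or the config file.

## Network geometry

Basal geometries are grown as $d$-dimensional simplicial complexes
($d = 1, 2, 3$): start from one $d$-simplex and repeatedly glue a new
$d$-simplex onto an existing $(d-1)$-face chosen with probability
$\propto e^{-\beta\varepsilon}(1 + \text{flavor}\cdot n_{\text{glued}})$.
With flavor 1 and $\beta = 0$ (the defaults) and $d = 1$ this is
preferential attachment and yields a scale-free degree distribution; the
exact structural identities $|E| = d|V| - d(d+1)/2$ hold for every $d$.
Basal geometries are merged by adding, per iteration, exactly
$\max(1, \operatorname{round}(\text{edge\_rate}\cdot|V|))$ new distinct
edges between random non-adjacent pairs (collisions resampled, so the
count is exact; defaults `edge_rate = 0.02`, one iteration — the
proportionality to the graph order is stated, the constant is a repository
choice).

The growth process produces an *undirected* complex; how it becomes a
directed activator/repressor network is not specified by the model, so we
make the simplest generative choice: each edge is oriented uniformly at
random and labelled activating with probability `activation_fraction`
(default 0.5). Self-loops never arise (the diagonal is validated zero),
and `A` and `R` partition the edge set, so $N = A + R$ with disjoint
supports by construction. An alternative worth noting for future work is
orienting edges old-to-new from the growth order; we did not adopt it
because it ties regulatory direction to node age, an assumption the model
does not make.

Connectivity diagnostics fit a discrete power law to each degree tail by
maximum likelihood with KS-selected $x_{\min}$ (Hurwitz zeta evaluated by
truncated summation with an Euler–Maclaurin tail); fits are flagged
non-converged for degenerate (all-equal-degree) inputs or tails with fewer
than 10 observations.

## What the synthetic-data generator states

The generator's world is the case-study configuration: allele counts
sampled i.i.d. uniformly from {0, 1, 2} (50 loci, one gene per locus; the
full-size study uses 5000 individuals, the scaled-down test world 200); 12
of 50 loci designated core with equal weights $1/12$; the network grown as
a pure $d = 1$ complex. Features of real data it deliberately does **not**
emulate: linkage and allele-frequency structure (entries are i.i.d.),
pedigree, any feedback from trait to genotype, transcription-factor
biochemistry beyond the equilibrium occupancy model, and translational
regulation. A green test therefore establishes internal correctness of the
mechanism and its stated trends — not realism of any particular organism's
architecture.

## Numerical choices

* **Stochastic mode** uses fixed-step Euler–Maruyama with
  $\Delta t = 5\times10^{-4}\,T_{\max}$ — exactly 2000 steps regardless of
  the span. Noise is multiplicative on both blocks,
  $c \leftarrow c + f(c)\Delta t + \gamma c \eta$,
  $\eta \sim N(0, \sigma_q^2 \Delta t)$; the diffusion coefficient
  $\gamma\sigma_q$ is state-independent. Negative excursions are clamped to
  0 after each step (concentrations are physical). Being first-order with a
  mandated step count, its trajectory accuracy has a floor of a few
  $10^{-3}$ relative on systems that relax during the run; tests assert
  exactly that, not more.
* **Delay/deterministic mode** uses the Bogacki–Shampine embedded 3(2)
  pair with FSAL, adaptive steps (initial step from the initial slope,
  growth capped at 5×, shrink at 0.2×), cubic-Hermite interpolation of the
  accepted history for the delayed state, and constant pre-history equal to
  the initial state for $t \le 0$. With $\tau > 0$ the step is capped at
  $\tau$ so stage lags always fall in accepted history (method of steps);
  both the translation delay $x(t-\tau)$ and the regulation delay
  $s(t-\tau)$ use the same $\tau$.
* **Initial value** is the all-ones state; **time averages** are
  trapezoidal over the final 80% of the span with the window boundary
  linearly interpolated, exact for piecewise-linear trajectories and
  correct on the non-uniform grids the adaptive solver produces.
* **Expression-rate truncation**: $P \sim N(P_\mu, \kappa P_\mu)$ is
  resampled below $10^{-6} P_\mu$. At small $P_\mu$ this visibly shrinks
  the variance below $\kappa P_\mu$ (closed-form truncated-normal moments
  are used as the test oracle); at the default $P_\mu = 10$ the effect is
  negligible.
* **Tie-break** for the reference genotype's modal allele count: smallest
  code wins, making the reference deterministic.
* **Common random numbers across the $\kappa$ grid**: the G×G study reuses
  the same seed for each $\kappa$, so the expression-rate draws are paired
  and the variance comparison across $\kappa$ is a paired design. At
  $\kappa = 0$ the sampling collapses to $P \equiv P_\mu$ exactly, making
  the zero-variance identity exact.

## G×E composition and variance components

Per environment replicate, each gene's transcription-rate *expectation* is
resampled from $N(\mu_x, \phi\mu_x^2)$ (truncated positive) and the
genotype effect applies multiplicatively on top ($K_{x,j} = P_r \odot
M_{j\cdot}$), preserving the marker-effect matrix's role; the composition
order is a declared choice. The environmental variance component is
estimated as $\sigma_e^2 = \operatorname{mean}_r
\operatorname{Var}_j(y_{jr} - y_j^{(g)})$ — the replicate-averaged variance
of deviations from the genotypic value — a declared estimator chosen for
its exact $\phi = 0 \Rightarrow \sigma_e^2 = 0$ degeneration. $\omega$
(the proportionality between $\phi$ and the environmental variance) is
accepted in the interface but only $\phi$ enters computation. The trait is
reported as computed — normalized by the reference, never centered — so
its mean sits near the core-weight sum and distribution shifts under
$\kappa$ are visible rather than removed.

## Determinism and parallelism

Every per-genotype random stream is seeded from (master seed, genotype
index), so results are independent of execution order: worker counts 1, 2
and 8 produce byte-identical output files, which the tests assert at the
file level. The paired-seed scheme keeps all derived seeds below $2^{31}$.

## Known limitations

* The Euler–Maruyama step rule is honored as stated; users needing tighter
  deterministic accuracy should use the RK mode.
* The power-law fit reports a point estimate without standard errors or a
  goodness-of-fit p-value; it is a diagnostic, not an inference procedure.
* With `flavor = -1` and $d = 1$ every face saturates after one gluing and
  growth can halt; the error message says so. Flavors 0 and 1 always grow.
* The in-vivo network import pathway is the generic adjacency reader only.
* Trait values are nonnegative by construction only when protein averages
  are positive, which holds for positive rates; zero reference products
  (possible only in pathological parameterizations) are a hard error.
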