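---
title: "Division of labor on interaction networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division of labor on interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dolnet)
```

## The model and its assumptions

`dolnet` models a clonal multicellular group as `N` cells on an undirected
interaction graph. Each cell invests a fraction `v` of one unit of effort in
viability and the remainder `b = 1 - v` in fecundity; returns are the
powers `v^alpha` and `b^alpha`. The exponent `alpha` is the return-on-
investment nonlinearity: above 1, returns accelerate (convex); below 1 they
saturate (concave). A cell's reproductive output is the *product* of its
fecundity returns and the viability returns it ends up holding, so a cell
with either quantity at zero contributes nothing.

Viability returns — and only viability returns — are shared. Cell `i`
passes a fraction `beta` of its viability returns, divided equally among
its `n_i = degree + 1` closed-neighborhood members (a cell always counts
itself, so it can never give everything away), keeping `1 - beta + beta/n_i`
in total. This defines the row-stochastic sharing matrix built by
`build_sharing()`; group fitness, evaluated by `group_fitness()`, is

    W = sum_i (1 - v_i)^alpha * sum_j c_ji v_j^alpha .

Assumptions worth keeping in view: cells are genetically identical, so
selection acts only between groups on `W`; the topology is fixed for a
group's lifetime; sharing is equal-split rather than weighted; and
fecundity returns are never shared (the `group_fitness_two_goods()`
generalization relaxes that last assumption but is not exercised by the
main analyses).

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha` | return nonlinearity | 1 | dimensionless, > 0 |
| `beta` | fraction of viability returns shared | 1 | dimensionless, [0, 1] |
| `n` | cells per group | 10 | count |
| `population_size` | groups under selection | 1000 | count |
| `generations` | Wright–Fisher steps | 1000 | count |
| `mutation_probability` | per group per generation | 0.02 | probability |
| `mutation_sd_fraction` | kernel sd as fraction of current value | 0.1 | dimensionless |

The simulation defaults are the study protocol sizes; the test suite runs
scaled-down versions (discussed below).

## Stability analysis and `alpha*`

At the generalist strategy `v = 1/2` the fitness gradient vanishes whenever
the sharing matrix is symmetric (equal degrees, uniform `beta`). Whether
that point is a maximum or a saddle is decided by the Hessian, implemented
analytically in `fitness_hessian()` from the second derivatives of `W`:

- diagonal `k`:
  `alpha (alpha-1) [v_k^(a-2) sum_j c_kj b_j^a + b_k^(a-2) sum_j c_jk v_j^a]
   - 2 alpha^2 c_kk v_k^(a-1) b_k^(a-1)`
- off-diagonal `(k, l)`:
  `-alpha^2 [v_k^(a-1) c_kl b_l^(a-1) + b_k^(a-1) c_lk v_l^(a-1)]`.

This differentiation is the package's own; it is validated two independent
ways in the test suite — against central finite differences of `W` on
random interior strategies, and against the closed-form largest eigenvalues
for the complete, ring, and balanced bipartite families,
`alpha (1/2)^(2 alpha - 3) (-1 + k alpha beta)` with coefficients 1, 4/3,
and `2N/(N+2)`. Generalists therefore destabilize at `alpha beta` products
of 1, 3/4, and `(N+2)/(2N)` respectively.

`alpha_star()` extends this to any topology: it is the `alpha` at which the
largest Hessian eigenvalue at `v = 1/2`, `beta = 1` crosses zero. For
irregular graphs (filaments, trees) the generalist is not a critical point
— the gradient is nonzero because `c` is asymmetric — so `alpha*` there is
a proxy for amenability to specialization rather than an exact bifurcation
point; `stability_report()` flags that case. One bookkeeping note: under
this convention the fully connected topology has `alpha* = 1`, the zero of
its own eigenvalue formula; accounts that quote `alpha* = 0.5` for the
well-mixed case are using a different normalization, and we deliberately
follow the eigenvalue formula.

```{r alpha-star}
sapply(c(4, 10, 50), function(n) alpha_star(make_topology("ring", n)))
sapply(c(5, 10, 20, 50), function(n) alpha_star(make_topology("filament", n)))
```

Ring `alpha*` is size-free; filament and tree `alpha*` decrease with size
and plateau by a few tens of cells.

## Numerical choices

- **Boundary powers.** `0^alpha` is 0 for all `alpha > 0`, so complete
  specialists are well defined even with saturating returns. Derivative
  factors like `v^(alpha-1)` diverge at the boundary for `alpha < 1`; the
  gradient and Hessian return signed infinities rather than raising, and
  callers clamp.
- **Root finding.** `alpha_star()` bisects the largest symmetric-eigenvalue
  curve over `alpha` in (0.01, 3], tolerance 1e-6, and returns `NA` when
  there is no sign change in the bracket.
- **Negative definiteness.** Eigenvalues must fall below `-1e-10 * N` — a
  scale-aware tolerance against round-off in the zero eigenvalue cases.
- **Optimization.** `maximize_fitness()` runs L-BFGS-B with the analytic
  gradient from multiple starts, box-clamped to `[1e-9, 1 - 1e-9]` because
  of the boundary singularity; since true optima often lie exactly on the
  boundary, each polished point is also snapped coordinate-wise to
  `{0, 1}` (fully, and for near-boundary coordinates only) and the snapped
  candidates scored exactly. The generalist and both alternating binary
  strategies are always candidates, so the result is never below the
  generalist fitness. Defaults: 20 random restarts (10 inside sweeps),
  first-found tie-break.
- **Specialist classification.** Phase and sparsity maps call a grid cell
  "specialist" when the specialization score `S` of the optimum (or the
  final population mean) exceeds 0.5, the same crossing used to read the
  simulation curves.

## Wright–Fisher protocol

Populations of groups evolve in discrete generations: each group has a 2%
chance of a strategy mutation (the whole investment vector redrawn from a
truncated Gaussian centered on the current strategy with sd one tenth of
each component), fitness is recomputed, and the next generation is drawn
with replacement with probability proportional to fitness *rank* (worst
rank 1; ties averaged). Rank weighting is linear — the simplest reading of
rank-proportional selection — and population size is exactly constant.
Because the mutation sd is proportional to the current value, a component
at exactly 0 is pinned; initial strategies are uniform draws and almost
surely interior.

In evolving-sharing mode each cell carries its own `beta`, starting at 0
(no sharing), and an independent 2% per-generation process mutates one
uniformly chosen cell's `beta` through the same truncated-Gaussian kernel.
Taken literally, "sd = 10% of the current value" makes `beta = 0`
absorbing; we therefore apply a configurable sd floor (default 0.01,
settable to 0 for the strict kernel) so sharing can arise from nothing.
Strategy mutation continues alongside `beta` mutation — sharing must evolve
together with specialization for specialists to be reachable at all. With
the default floor, sharing accumulates slowly: selection on `beta` is
nearly neutral until strategies begin to specialize, so on a 10-cell ring
at `alpha = 1.2` the population mean `beta` reaches roughly 0.3 only after
a thousand generations. Truncation to `[0, 1]` everywhere uses rejection
sampling with a 100-draw cap followed by clamping.

## What the synthetic experiments emulate — and what they do not

All experiments are self-contained: topologies are generated
programmatically and strategies/populations are simulated. The Erdős–Rényi
sweeps parameterize sparsity as the fraction of possible connections
present, and keep disconnected realizations (they are part of the ensemble,
not failures). The model abstracts away cell geometry, growth, positional
effects, and any within-group variation; passing tests therefore show that
the *network* mechanism behaves as the theory says, not that any particular
organism does. Balanced bipartite means the complete bipartite graph on
equal halves — the topology that maximizes assortment of complementary
specialists; trees are filled breadth-first with branching factors 2 and 3
standing in for the branched growth forms.

## Test-suite problem sizes

The test suite runs the same experiments at desk scale, chosen once as
sizes a referee could re-run while reading: phase maps via evolution use
populations of 200 for 200 generations on 10-cell topologies (classifying
grid cells at `alpha beta` distance at least 0.1 from the analytic boundary,
at least 90% correctly); sparsity sweeps use `n = 10` with 10 random graphs
per cell on the default 11 x 11 grid; kernel checks use 2-3 x 10^4 Monte
Carlo draws. Full-scale runs (1000 groups, 1000 generations, full grids)
use the same code paths and remain feasible in hours.

## Mean-field theory

For large `N` with `z` neighbors per cell at `alpha = beta = 1`:
generalists score `W_G = N/4`; complete specialists with fecundity fraction
`X` and assortment `f` (mean fraction of a fecundity specialist's neighbors
that are viability specialists) score `W_S = z f X N / (z + 1)`.
Specialists win iff `f > 1/(4X) + 1/(4Xz)` — at the balanced split,
`f > 1/2 + 1/(2z)` — which is unreachable both for well-mixed groups
(`f = 1/2`) and for `z = 1`, and impossible altogether when
`X <= 1/4 + 1/(4z)`. `measure_f()` evaluates `f` on concrete labeled
graphs; on irregular graphs it normalizes by each cell's own degree (the
mean-field `z` is undefined there), an extension flagged in the result.
"Favored" is the strict inequality `W_S / W_G > 1` throughout.

```{r meanfield}
f_threshold(z = 3)
f_threshold(z = 4)
measure_f(make_topology("balanced_bipartite", 10),
          rep(c("viability", "fecundity"), each = 5))
```

## Known limitations

- The mean-field formulas are specific to `alpha = beta = 1`; no extension
  to general parameters is provided.
- For asymmetric sharing the package does not locate the non-generalist
  critical point; `alpha_star()` remains a proxy there.
- Whether a graph realizing a prescribed `(f, z, X)` exists is a graph
  coloring question the package does not attempt.
- One discrepancy is knowingly left as computed: direct evaluation of the
  balanced-bipartite complete-specialist fitness gives `N^2 beta / (2N+4)`
  (25/6 at `N = 10`, `beta = 1`), and the package reports that value; the
  large-`N` behavior relevant to the sharing-evolution argument is
  unaffected.
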