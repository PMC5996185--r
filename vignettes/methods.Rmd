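---
title: "Methods: linear-quadratic control for expression-signature reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-quadratic control for expression-signature reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqrepurpose)
```

## The model and its assumptions

`lqrepurpose` treats a disease's gene-expression deviation from the
healthy equilibrium as the state of a discrete-time linear system,

$$x(t) = A\,x(t-1) + u(t-1), \qquad x, u \in \mathbb{R}^N,$$

where $u$ is an additive treatment acting directly on every gene (the
input-coupling matrix is implicitly the identity). The linear form is an
admittedly strong assumption — real regulatory kinetics are nonlinear and
the transition structure is not identified from time-series data — but it
has the equilibrium the biology requires (if $x = u = 0$, the state stays
at 0: no dysregulation, no treatment needed) and it admits exact optimal
control at pathway scale. Everything downstream uses only the *sign
structure* of the optimal control, which is far less sensitive to the
linearity assumption than magnitudes would be.

All three data layers are discretized to $\{-1, 0, +1\}$ (drug actions
also $\pm 0.5$). This deliberately sacrifices resolution for robustness:
no "normal range" per gene needs to be known, and the score below is
invariant to positive rescaling of the drug vector anyway.

## Building the dynamics matrix

Interaction mechanisms are quantified as $+1$ (activation), $-1$
(inhibition) and $0$ (catalysis, ptmod, binding, reaction, expression,
unknown — the catch-all). Score-bearing edges (STRING-style, 0–1000
scale) below **500** are dropped; scoreless edges from curated pathways
pass unconditionally. Parallel edges between the same ordered pair are
summed and clipped to $[-1, 1]$ — a package choice where the upstream
convention is silent; summation lets conflicting evidence cancel while the
clip preserves the discretized scale.

Two conventions deserve explicit statement:

* **Edge orientation.** A literal reading stores the effect of gene $i$
  on gene $j$ at entry $(i, j)$; but in $x(t) = A\,x(t-1)$ a *row* must
  collect *incoming* effects. The default layout therefore stores entry
  $(i, j)$ = effect of gene $j$ on gene $i$, so matrix–vector
  multiplication propagates influence along edges. The literal layout
  remains available (`layout = "paper-literal"`, CLI
  `--adjacency-layout`) for comparison.
* **Normalization.** The raw matrix $A^*$ is divided by $|\lambda|$, the
  magnitude of its largest eigenvalue. For a signed non-symmetric matrix
  $\lambda$ may be complex; dividing by the modulus is the only reading
  that keeps $A$ real. The result has spectral radius exactly 1 —
  *marginal* stability. The default reproduces that behaviour;
  `stability_margin = ε` divides by $|\lambda|(1+ε)$ when strict
  stability is wanted. A nilpotent $A^*$ (all eigenvalues 0) is left
  unchanged with normalization recorded as 0.

## The expression signature

From a GEO2R/limma top-table, genes with adjusted $p > \alpha$ (default
**0.05**) are set to 0; significant genes take $\mathrm{sign}(\log FC)$.
Boundary and degenerate cases are fixed as: $p = \alpha$ is **kept** (only
strictly larger is filtered); $\log FC = 0$ with significant $p$ maps
to 0; duplicate probe rows resolve to the smallest adjusted $p$ (the most
confident probe — deterministic). Whether the fold-change is base-2 or
base-10 is irrelevant since only its sign is used. Malformed rows are
skipped and counted, never silently coerced.

## The optimal intervention

The infinite-horizon LQR objective
$J = \sum_t x(t)^\top x(t) + u(t)^\top u(t)$ (state and control weights
both identity — fixed, not configurable, to match the unweighted
objective; weighting is a documented extension point) leads to the
discrete algebraic Riccati equation

$$A^\top P A - P - A^\top P (P + I)^{-1} P A + I = 0.$$

The solver iterates $P \leftarrow A^\top P A - A^\top P (P+I)^{-1} P A + I$
from $P_0 = I$ — the value-iteration recursion — to max-abs update below
`tol` (default $10^{-10}$, cap 10 000 iterations). Because $B = I$ the
system is always stabilizable and $Q = I$ makes it fully observable, so a
unique stabilizing $P \succ 0$ exists *even at spectral radius 1*, the
marginal case the normalization produces; in practice the closed-loop
radius lands well inside the unit circle (≈ 0.3–0.4 on sparse signed
networks) and the iteration converges in tens of steps. Non-convergence
is an error carrying the last residual, never a silent fallback. Each
returned solution is symmetrized against round-off drift and ships with
its residual and closed-loop spectral radius as diagnostics.

The ideal intervention is the first optimal control step

$$u(0) = -(I+P)^{-1} P A\, x(0);$$

later steps decay quickly and are not used for scoring. Its sign pattern
uses a zero threshold of $10^{-12}$: entries are generically nonzero
floats, and exact zeros arise only for genes structurally unreachable
from the dysregulated set.

## Therapeutic score and evaluation

$$T_d \;=\; \frac{\sum_i u_d(i)\,\mathrm{sign}(u(0))(i)}
                 {\sum_i |u_d(i)|\,|\mathrm{sign}(u(0))(i)|} \in [-1, 1].$$

The numerator is **signed**. A typeset variant wraps it in absolute value,
which would force $T_d \ge 0$ — inconsistent with a score that is
"decremented when opposite", spans $[-1, 1]$, and takes negative values on
withdrawn drugs; the signed form is the only internally consistent
reading. The literal variant stays available (`abs_numerator = TRUE`).
A zero denominator (the drug touches no gene the intervention touches)
yields an **undefined** score, reported as `NA` and never silently as 0;
`undefined_as_zero = TRUE` reproduces a zero-filling convention for
comparison. Drug-action labels are quantified by the packaged 37-label
table (overridable via `mechanism_table(path)`); DMAP-style score-bearing
rows below **800** are dropped, scoreless DrugBank-style rows pass.
Multiple mechanisms of one drug on one gene are summed by default
(opposing actions cancel; `mean` offered) — $T_d$'s denominator normalizes
per-drug scale away regardless.

D1-vs-D2 separation uses the Mann–Whitney AUC (ties count one half),
verified in the suite against brute-force pair counting; rankings break
ties alphabetically so output is deterministic. No train/test split is
used: neither model construction nor scoring consumes the drug labels.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` produces the statistical *shape* of the real
inputs: a sparse signed Erdős–Rényi interactome, a $\{-1,0,+1\}$
signature emitted as a genuine GEO2R-dialect table (so the reader and
discretizer run end to end), and drug panels with planted truth — "good"
drugs target genes where $u(0)$ is nonzero with mechanisms matching its
sign (so at zero noise $T_d = 1$ by construction), "bad" drugs oppose it
($T_d = -1$), "random" drugs draw uniformly. Defaults state a
pathway-sized world: $N = 100$ genes, edge density 0.05 (≈ 500 edges,
comparable to curated disease pathways of a few hundred genes and
interactions), 30 % inhibitory edges, 20 dysregulated genes, panels of
10 + 10 drugs with 5 targets each. Planting is done against the LQR
intervention by default so the planted-truth test exercises the whole
scoring chain; `plant_against = "signature"` plants against simple
signature reversal instead.

What it does **not** emulate: scale-free/motif topology, correlated
probe noise, alias ambiguity in gene identifiers, biotech drugs, or
multi-drug regimens. A green planted-truth test therefore establishes
that the pipeline recovers a signal it is mathematically guaranteed to
contain — it says nothing about performance on real interactomes, which
require externally downloaded data outside this package's scope.

One global seed fans out into fixed per-stage substreams (network,
signature, drugs), so stages regenerate independently and scenarios are
bit-for-bit reproducible; the generator restores the caller's RNG state.

## Numerical choices, in one place

| quantity | default | domain / note |
|---|---|---|
| interactome confidence floor | 500 | 0–1000; score-bearing rows only |
| drug-interaction confidence floor | 800 | 0–1000; score-bearing rows only |
| significance α | 0.05 | $p = α$ kept |
| Riccati update tol / max iter | 1e-10 / 10 000 | non-convergence errors |
| sign threshold on $u(0)$ | 1e-12 | below ⇒ sign 0 |
| stability margin | 0 | marginal, matching the source normalization |
| trajectory horizon | 500 | tail warning if final state norm > 1e-8 |
| aggregation (drug, PPI) | sum, clip to $[-1,1]$ (PPI) | `mean` optional (drug) |

## Known limitations

* Linearity and three-level discretization cap score resolution; two
  drugs with equal sign structure but different potency tie.
* Gene identifiers are matched as trimmed, case-folded opaque strings;
  alias/UniProt resolution is the curator's job.
* Undefined scores are excluded from ROC (with a warning), which silently
  shrinks the evaluated panel when drugs have no model overlap.
* The Riccati solve is $O(N^3)$ per iteration — comfortable at pathway
  scale ($N \lesssim 10^3$), a bottleneck beyond it.
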