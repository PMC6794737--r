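---
title: "Methods: two-phase Design-of-Experiments optimization of pipeline parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase Design-of-Experiments optimization of pipeline parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doeopt)
```

## The problem

Bioinformatics pipelines — assemblers, classifiers, variant callers chained
together — expose many tunable parameters whose effects interact and are
hard to predict. Exhaustively evaluating the parameter grid (grid search)
grows exponentially with the number of parameters, while ad-hoc manual
tuning is unsystematic. `doeopt` treats the pipeline as a black box and
applies statistical Design of Experiments (DoE): run the pipeline at a
carefully chosen, small set of parameter configurations (*factors* at
*levels*), model the measured outcomes (*responses*), and refine.

## The two phases

### Phase 1 — GSD screening

Each numeric factor gets a small number of equally spaced **screening
levels** across its global `[min, max]` range (default 5; ordinal factors
are rounded half-up to integers, and rounding collisions are an error
rather than a silent merge). Categorical factors contribute their category
list. Instead of the full factorial over these levels, a **generalized
subset design (GSD)** is executed: level indices of each factor are
partitioned cyclically into `r` residue classes (`r` = the *reduction
factor*, default: the number of factors) and the design keeps exactly the
full-factorial cells whose class labels sum to a fixed residue modulo `r`.
The `r` complementary designs so defined are pairwise disjoint and tile the
full factorial — each is a balanced, near-orthogonal `1/r` fraction.

Screening serves two purposes: it locates an approximate optimum at coarse
resolution, and it **fixes categorical factors** at the categories of the
best screened run; phase 2 then optimizes numeric factors only.

### Phase 2 — iterative response-surface refinement

The best screening configuration becomes the center of the first
optimization region. If that configuration sits on a factor's global min or
max, the center shifts one screening level inward; the working low/high
settings are the midpoints between the center and its neighboring screening
levels, and the **span** is `high − low` (this is why at least three
screening levels per numeric factor are required).

Each iteration then:

1. builds a **face-centered central composite (CCF)** design — `2^k`
   corners, `2k` face-centered axial points, one center point — over the
   active factors, decoded affinely into the current `center ± span/2`
   region (ordinals rounded half-up, duplicates merged);
2. executes and scores the runs;
3. fits an OLS response-surface model per response, selecting terms from
   intercept + linear + two-way interactions + pure quadratics (exactly
   what a CCF can estimate) by **best-subset** search (up to 4 factors) or
   **greedy forward** selection (above 4), maximizing the cross-validated
   predictive power **Q2 = 1 − PRESS/SST** with leave-one-out PRESS;
4. if every response model has Q2 above the threshold (default 0.5), the
   model optimum inside the region — found by dense grid search, 51 points
   per factor, exhaustive integer enumeration for small ordinal ranges —
   is executed as one extra **validation run**;
5. the design space is updated toward the iteration's best executed point:
   per factor, if the best point is further than 25% of the span from the
   center, the center moves by one step (25% of the span); every span then
   contracts by the **shrinkage factor** (default 0.9); a region pushed
   past a global bound is translated back inside at unchanged span;
6. the loop halts when no factor moved, when the iteration's best did not
   improve on the previous iteration's best (the screening best, for
   iteration 1), or at an iteration cap (default 25).

If the best run at convergence still has some response outside its
acceptable limits (desirability 0), the optimization phase restarts from
the next-best *distinct* screening configuration, up to 3 restarts. The
final answer is the best configuration over **all** executed runs, and the
full audit trail is retained.

## Multiple responses: desirability

With several responses, each is rescaled to a Derringer–Suich desirability
in `[0, 1]`: 0 at or outside its acceptability limit, 1 at or beyond its
target, linear in between (exponents fixed at 1; a `target` criterion uses
a piecewise-linear tent). The overall score is the unweighted geometric
mean, so one unacceptable response zeroes the whole run. Runs are ranked —
and the design space moved — on this overall desirability. Single-response
problems bypass desirability and compare raw values under the declared
criterion; limits are then optional (and without limits the restart rule
never triggers, since no "minimally acceptable value" exists).

In multi-response mode one OLS model is fitted per response; the Q2 gate
requires *every* model to pass, and the validation-run search maximizes the
overall desirability of the per-response predictions.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `levels` | 5 per numeric factor | screening resolution; cost grows as `levels^k / reduction` |
| `reduction` | number of factors | GSD fraction `1/r` of the screening grid |
| `shrinkage` | 0.9 | span contraction per iteration; closer to 1 = slower, steadier convergence |
| `step_fraction` | 0.25 | movement step and movement threshold, as a fraction of the span |
| `q2_threshold` | 0.5 | minimum leave-one-out Q2 before the model optimum is trusted |
| `model_selection` | auto | best-subset up to 4 active factors, greedy forward above |
| `n_grid` | 51 | grid points per factor in the optimum search; lower it for k > 4 |
| `restarts` | 3 | attempts from next-best screening points when limits unmet |

## Numerical choices

* **Q2 scheme.** The cross-validation scheme behind Q2 is not prescribed by
  the method's description; leave-one-out was chosen because iteration run
  counts are small (9–25). PRESS is computed exactly through the hat
  diagonal, which is algebraically identical to refitting without each
  point; the test suite verifies this against explicit refits.
* **Fitting units.** Models are fitted in coded `[-1, 1]` units (per-column
  affine map over the design's range) for conditioning; coefficients are
  reported in both coded and natural units. The least-squares solve uses
  the Cholesky factor of the normal equations — the design matrices are
  tiny and well conditioned in coded units — with rank deficiency detected
  and reported with the collinear terms named.
* **Degenerate responses.** A constant response (SST ≈ 0) gets `r2 = 1`,
  `q2 = 0`: the fit is exact but carries no cross-validatable signal, so
  the predictivity gate fails and no validation run is wasted.
* **Ties.** Run ranking breaks ties on the lowest run id; the grid search
  for the model optimum breaks ties toward the configuration closest to the
  region center (Euclidean, coded units), then lexicographically. Ordering
  within designs is lexicographic. All of this makes audits reproducible.
* **Rounding.** Half-up (toward +∞) everywhere an ordinal value is
  produced: screening-level construction, coded decoding, and percentage
  reporting (one decimal).
* **Frozen factors.** A span that falls below the minimum resolution
  (1 for ordinals, 1e-9 of the global range otherwise) freezes its factor
  at the current center with a warning; frozen factors leave the CCF.
* **No term hierarchy.** An interaction may enter a model without its
  parents — simpler, and it matches how greedy selection behaves.

## The synthetic world

The mock objectives (`mock_objective()`) emulate what a well-behaved
pipeline-quality surface looks like near its optimum: a concave quadratic
over the numeric factors (`y = y0 − Σ c_f (x_f − opt_f)² + Σ w_fg (x_f −
opt_f)(x_g − opt_g)`), additive offsets per category, optionally Gaussian
noise seeded per configuration (hash of seed and settings) so parallel and
sequential execution agree run by run. Multi-response mocks emit affinely
transformed copies with shifted optima, so response goals genuinely
conflict and desirability aggregation is exercised nontrivially. The
randomized test problems keep interaction weights below `0.3·√(c_f·c_g)`,
i.e. strictly concave and near-separable — a deliberate statement of the
benign-geometry assumption under which the method's movement rules are
expected to track the optimum.

What the mocks do **not** emulate: plateaus and cliffs (e.g. an assembler
collapsing beyond a k-mer bound), discrete jumps in responses, heavy-tailed
or configuration-dependent noise, and multimodality beyond the two-basin
fixture used to exercise the restart rule. A green optimizer test therefore
establishes that the machinery implements the stated rules and recovers
optima of benign surfaces with far fewer runs than grid search — not that
any real pipeline's response surface is this friendly.

## Known limitations

* A single numeric factor gives a degenerate 3-point CCF after
  deduplication; a quadratic cannot be cross-validated on it, so the Q2
  gate usually fails and progress relies on movement toward observed best
  points. Two or more numeric factors are the intended regime.
* The dense-grid optimum search costs `n_grid^k` model evaluations; beyond
  4 active factors reduce `n_grid` (the CCF itself is capped at k = 8).
* The movement/shrinkage loop, like the method it implements, is a local
  refinement: with strongly multimodal surfaces it relies on screening (and
  the restart rule) to land in the right basin.
* Scheduler support is header passthrough (`#SBATCH` lines) with local
  execution; no live cluster interaction is attempted or tested.
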