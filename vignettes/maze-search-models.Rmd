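---
title: "Planning models for maze search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning models for maze search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazeplan)
```

## The task and its state space

An agent navigates a 2-D grid maze of walls, corridors, and *rooms* —
clusters of initially hidden tiles that are revealed together the moment
any of their tiles enters the agent's line of sight. One room tile hides
an exit, a priori uniform over all hidden tiles; the agent's objective is
to reach it in as few steps as possible. Because rooms are revealed in
discrete, all-at-once events, the relevant planning problem is not
tile-level navigation but choosing the *order of observations*. The
package represents this as a decision tree whose nodes pair a vantage
tile with the set of rooms observed so far; each node carries

* `s` — steps from the parent vantage to this vantage;
* `e` — the mean walking distance from the vantage to a newly revealed
  tile, i.e. the expected distance to the exit if it is found here;
* `p` — newly revealed tiles over all tiles still unobserved, the
  probability the exit is found at this node given it was not found
  earlier;
* `cells` — the number of tiles revealed.

Along any root-to-leaf path the unconditional find probabilities
`p_i * prod_j (1 - p_j)` sum to one exactly (a tested invariant), so
every cost model below is an expectation over a complete event
partition.

## Line of sight

Visibility follows an isovist rule on unit tiles: a target tile is
visible when its entire area can be seen from somewhere in the
observer's tile. We discretize this with corner segments: each of the
target's four corners must be joined to at least one of the observer's
four corners by a segment whose intersection with every (closed) wall
square has zero length — so segments grazing exactly along a wall edge
count as blocked, which is what makes a tile diagonally across a wall
corner invisible. Two deliberate refinements:

* **Symmetrization.** The raw corner rule is not symmetric on irregular
  layouts (the quantifier "every target corner, some observer corner"
  changes meaning when the roles swap). We define visibility as the
  conjunction of both directions, which is strictly more conservative,
  preserves all the motivating examples, and makes "b visible from a"
  and "a visible from b" provably identical — an invariant the test
  suite asserts on arbitrary wall soups.
* **Tangency is occlusion.** Continuously, a sight line that threads
  exactly through a lattice corner point between two diagonal walls is
  unobstructed but has measure zero. The package treats such tangent
  rays as blocked, and the continuous sampling oracle used in the tests
  mirrors this by dilating walls by a small clearance (0.005 tiles).

A practical consequence worth knowing: under this strict rule, a room is
fully visible from a single tile essentially only when the open region
formed by the room plus the vantage is a straight width-one channel (or
a union of such channels meeting at the vantage). The synthetic maze
generator and the hand-coded fixtures are designed inside this geometry;
`validate_maze()` flags any maze where a room would be revealed before
it is fully in view (a "partial visibility hazard").

## Cost models

With softmax temperature `tau` (steps-scaled; `tau -> 0` is
deterministic cost minimization, large `tau` approaches random choice),
the planner family is the recursion

`C(N) = s + w_p * e + disc * w_q * min_children C`

with `(w_p, w_q, disc)` equal to `(p, 1-p, 1)` for expected utility
(EU), `(p, 1-p, gamma)` for discounted utility (DU, `gamma` in [0,1]
acting as a planning-horizon limit), `(pi(p), pi(1-p), 1)` for
probability weighting (PW, `pi(p) = exp(-|ln p|^beta)`), and
`(pi(p), pi(1-p), gamma)` for PW-DU. At leaves the child term vanishes.
Boundary conventions: `pi(0) = 0` and `pi(1) = 1` for all `beta > 0`;
at `beta = 0`, `pi(p) = exp(-1)` on the open interval with the endpoints
kept at 0 and 1 by continuity in `p`. Ties in the child minimum break
toward the lowest node id, deterministically.

Heuristics score only the immediate node: `Steps` (`C = s`), `Cells`
(`C = -cells`), `Steps-Cells` (`C = k s - (1-k) cells`, `k` in [0,1]),
their numerosity-distorted variants, and `Random` (`C = 1`).

### Numerosity channel

Approximate number perception is modeled as a capacity-limited channel:
counts `n` in 1..80 are drawn from a Zipf-like prior proportional to
`1/n^2`; the conditional distribution `Q(k|n)` minimizes the expected
relative squared error `((n-k)/n)^2` subject to mutual information at
most `B` bits (`B` in [0.1, 10]). We solve this by alternating
minimization at a fixed information price with an outer bisection on the
price to meet the constraint (inner tolerance 1e-8 on expected
distortion, 1e-3 bits on the constraint, iteration caps raise errors
rather than returning silently). The expected estimate
`q(n) = sum_k k Q(k|n)` is pooled by isotonic regression to remove small
non-monotone wiggles the discrete reproduction alphabet leaves in
low-prior regions.

Two properties of this formulation should be kept in mind when reading
results. First, the mutual information achievable is bounded by the
prior's entropy (about 2.25 bits), so any `B` above roughly 2.3 yields
the exact identity channel — "high B counts exactly" is implemented
literally. Second, as `B -> 0` the percept collapses to the
*distortion-minimizing* constant, which under relative error sits near
the low end of the domain rather than at the prior mean; what matters
for the cost models (and what the tests assert) is that all counts
become indistinguishable. Distortion is applied to `s`, `cells`, the
remaining-total count, and to each within-room distance before
averaging into `e`; `p` is recomputed as `q(cells)/q(remaining)`, and a
zero count maps to zero.

### Monte Carlo tree search

The Sampling model approximates EU with a budgeted search: UCB1
selection in minimization form (`Q_j - c * sqrt(2 ln N / n_j)`),
expansion of one uniformly random unexpanded child per iteration, a
uniform-random rollout to a leaf valued by exit-probability-weighted
expected steps, and mean-cost backup. `mcts_plan()` reports root-child
visit proportions; because proportions can be exactly zero (which would
give degenerate likelihoods), model fitting and simulation instead pass
the backed-up child cost estimates through the softmax, with unvisited
children assigned the worst visited cost plus one. Budget counts
iterations; everything is reproducible from a seed.

## Fitting and comparison

Models are fitted per individual by grid search (the discrete likelihood
surface is multi-modal, so no gradient method): `tau` log-spaced on
[0.01, 10] (31 points), `gamma` in steps of 0.05, `beta` 0.1..2 by 0.1
plus {2.5, 3}, `B` on a coarse cached grid, `k` by 0.1; a reduced grid
(`coarse_grids()`) is used for large simulation studies and noted
wherever it is. The training objective adds the improper log-prior
`-ln tau` (a 1/tau prior on the softmax temperature; uniform on all
other parameters) to the training log-likelihood; fivefold
cross-validation is seeded per participant, and performance is the total
test log-likelihood over folds. Decisions at single-child nodes carry no
information and are excluded at the source (the simulator never emits
them). Cost vectors are memoized per (maze, model, parameter combination)
and shared across participants, which is what keeps cohort-scale studies
within minutes.

Aggregate analyses mirror the individual ones: per-maze first-choice
frequencies across participants, Pearson correlation with a model's
predicted choice probabilities at the cohort's mean fitted parameters,
and participant-level bootstrap confidence intervals (including the
bootstrap distribution of a difference between two models'
correlations).

## Decision times

Each decision record carries a time in milliseconds; initial decisions
(at the tree root, where a representation is formed and any plan is
laid) and subsequent decisions (inner nodes) are analyzed separately by
ordinary least squares at the level of the individual decision, with the
deciding participant's fitted parameters as predictors (`tau`;
plus `gamma`; plus `B`; or `gamma` plus `b = |beta - 1|`, depending on
the model). No time transformation or outlier exclusion is applied by
default.

## The synthetic world

Because no human dataset ships with the package, all empirical structure
comes from a generator with known parameters, and every test should be
read with its scope in mind.

*Mazes* are "combs": a corridor backbone with vertical stems; each stem
dead-ends in a vantage tile from which a straight width-1 pocket room
extends perpendicularly, so rooms are invisible until their vantage,
fully visible from it, and invisible from the start. Beyond six rooms
the backbone is split into segments joined through single-tile gate
rooms inside corridor jogs, which throttles the combinatorics of
observation orders (a 10-room maze builds about 25k tree nodes; a
configurable cap of 50k guards against blowup). This family exercises
the full model machinery but is narrower than hand-designed stimuli:
room shapes do not vary freely (a pocket of length L has mean exit
distance (L+1)/2), and corridors are width one. The hand-coded fixtures
supply the discriminating geometries the generator cannot produce —
most notably a design where two observations tie exactly on steps,
cells, and probability while differing in exit-distance spread, which
only a discounted planner can break (realized as one long room versus
two co-revealed flanking pockets).

*Cohorts* draw a generating model and parameters per participant
(uniform within configurable ranges), simulate every maze with softmax
choices over the generating model's costs, and attach decision times
linear in the generating parameters with Gaussian noise (SD 400 ms,
floored at 100 ms). The default time coefficients — initial
`2880 - 163 tau + 530 gamma`, subsequent `1069 + 55 tau - 134 gamma` —
take their magnitudes from the reported human-scale regressions so that
sign-recovery tests run at realistic signal-to-noise. All randomness
fans out from one master seed through labeled child seeds, and rerunning
any pipeline step with the same configuration and seed reproduces its
outputs byte for byte.

A green synthetic test therefore establishes that the estimation
machinery is correct and identifiable *in this stated world*; it says
nothing about which model best describes people, and the package makes
no such claim.

## Degenerate inputs and numerical conventions

Empty option lists, non-positive temperatures, out-of-range `gamma`,
`beta`, `B`, and counts below 1 raise immediate errors; counts above 80
clamp with a warning. Softmax uses a max-shift; path probabilities are
checked to 1e-12; EU-against-enumeration comparisons to 1e-9; reduction
identities (`DU(gamma=1)`, `PW(beta=1)`, `PW-DU(1,1)` against EU) to
1e-12 node-by-node. Mazes whose rooms cannot all be brought into sight
raise an unobservable-room error during tree construction rather than
producing a truncated tree.

## Known limitations

* The corner-rule isovist is conservative: geometries a human player
  could arguably see into (wide rooms entered mid-side) have no valid
  single vantage here, which constrains maze design more than the
  original task software would.
* Costs are recomputed at every node (Markovian agents); within-trial
  consistency of a precomputed plan is not modeled.
* The Sampling model's likelihood uses MCTS value estimates rather than
  visit proportions, and its stochastic likelihood makes grid fitting
  expensive; it is excluded from default model-comparison lists.
* The exact psychophysical channel the numerosity model references is
  specified here as rate-distortion with relative squared error; other
  distortion choices would move `q` at low `B`.
* No hierarchical pooling across participants; each individual is fitted
  independently, as in the analyses the package mirrors.
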