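---
title: "Synthesizing Boolean regulatory models by Monte Carlo tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing Boolean regulatory models by Monte Carlo tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolsynth)
```

## The modelling problem

Many regulatory phenotypes are naturally described as steady states of a
Boolean network: each species (gene, protein, complex) holds a binary
state, and a logic rule determines its next state from the current global
state. Building such a model by hand means choosing, from a combinatorially
large space of possible interactions, a rule set whose attractors match the
observed expression patterns. `boolsynth` automates that construction: it
searches the space of interaction sets with Monte Carlo tree search (MCTS),
scoring every candidate model by how closely its simulated attractors match
a reference census of observed states, and retains *every* scored model so
that the resulting model family — not a single "best" network — can be
mined for mechanisms.

## Model class and its assumptions

Update rules are restricted to **dominant inhibition**:

$$x^{t+1} = (\mathrm{act}_1^t \lor \dots \lor \mathrm{act}_n^t)
            \land \lnot (\mathrm{inh}_1^t \lor \dots \lor \mathrm{inh}_m^t)$$

where each $\mathrm{act}_i$ / $\mathrm{inh}_j$ is a single species or an
AND-composite of species. Any active inhibitor silences the target; a rule
with no activators is constant false; species without a rule are external
inputs and hold their initial value throughout a simulation. This form
keeps the action space small (one added interaction = one new term) while
expressing most curated rules. Logic that does not fit — constitutive
transcription, activation by *absence*, self-persistence with removal — is
carried verbatim as a rule's *frozen clause* (a DNF expression OR-ed into
the activator side). Frozen clauses are opaque to the structural layer:
they contribute no interactions, and the fixture instead records companion
prespecified edges so the structural accounting stays faithful.

Simulation is synchronous and deterministic, so every trajectory reaches a
fixed point or a cycle; the simulator detects both by exact-match history
lookup. A cyclic attractor is represented by the elementwise mean of its
cycle states — a fractional state, treated downstream like any other, on
the view that steady-state measurements are noisy snapshots of such cycles.
Two cycles with identical means merge into one census entry. Asynchronous
updating is out of scope.

### Knockout semantics

`knockout_gene()` removes every interaction into and out of a gene (all
cells); emptied rules become constant false, which reproduces null-mutant
behavior. `knockout_interactions()` removes specific edges; a rule stripped
of its *last* interaction is silenced entirely — its frozen clause is
dropped with it. The rationale: the frozen clause encodes pre-specified
regulation attached to the rule; once every interaction of the rule is
knocked out, modelling the target as an unregulated null gene is the
behavior that reproduces reported interaction-knockout phenotypes (in the
segment polarity fixture, deleting the `EN -| ci` edges silences `ci`
rather than making it constitutive, collapsing the CI/CIA/CIR arm — see the
package tests). With the alternative (clause survives), removing an
inhibitor could only ever *increase* its target, and interaction knockouts
of single-edge rules would be no-ops.

## Scoring: a greedy attractor edit distance

A model is simulated once from each initial state of a condition, giving a
census $\{(s_i, c_i^M)\}$ of attractor representatives with occurrence
counts; the reference data supply $\{(d_j, c_j^D)\}$ with the same total
$N_c$. The distance repeatedly picks the pair with the smallest Manhattan
distance among (simulated, reference) states with remaining supply and
demand, transfers $k = \min(\text{supply}, \text{demand})$ occurrences at
cost $\text{distance} \times k$, and accumulates

$$D_{edit} = \frac{\sum_k C_k}{|s| \cdot N_c} \in [0, 1],$$

normalizing by the number of species $|s|$ times $N_c$, the maximum
possible cost. Similarity is $1 - D_{edit}$; multi-condition problems take
the unweighted mean over conditions, applying each condition's gene
knockouts before simulating.

Numerical conventions worth stating:

* the transfer quantity is $\min(\text{supply}, \text{demand})$ — the only
  reading consistent with termination, since an occurrence-count
  *difference* can exceed the available supply;
* ties among equal-distance pairs break to the lexicographically smallest
  (simulated state, reference state) pair under the canonical species
  order, making scoring fully deterministic;
* the greedy procedure is the specified behavior; it upper-bounds the
  optimal transport cost and coincides with it whenever a zero-cost perfect
  matching exists (both properties are under test). No optimal-transport
  scorer is offered.

## Search

MCTS grows the model one committed interaction per step. Each step runs a
budget of iterations; an iteration selects a tree branch by upper
confidence bound, expands one child, completes the model with a uniform
random rollout up to the depth target (`max_steps` total added
interactions), simulates and scores the terminal model over all conditions,
and backpropagates. The selection value of a child reached by action $a$ is

$$(1 - \beta)\,\bar{Q} + \beta\,\bar{Q}_{RAVE}(a)
  + c\,\sqrt{\ln N_{parent} / n}$$

with $\beta = \sqrt{k_{RAVE} / (3 n + k_{RAVE})}$. Defaults: exploration
constant $c = \sqrt{2}$ and RAVE equivalence $k_{RAVE} = 1000$ — standard
values, both exposed in `search_config()`, since the source experiments
sampled them randomly and report no particular setting. Unvisited children
are explored before any visited sibling, in seeded-shuffled order.

Three refinements are always available and on by default: **RAVE**
(all-moves-as-first statistics shared across branches), **nested search**
(the step commits the first action of the best rollout seen during the
step, rather than the most-visited child), and **branch retention** (the
committed child's subtree, statistics included, becomes the next root). The
committed working model itself is also simulated and archived each step, so
a perfect intermediate model satisfies the stopping rule. A search stops at
`max_steps` committed interactions, or once a perfect score exists and
`min_steps` (default 8) steps are complete.

The candidate-action list is regenerated implicitly at every node: actions
already present, actions whose opposite-sign duplicate is present, and
(optionally) actions exceeding a per-rule term cap are invalid. Every
distinct simulated model enters a deduplicated archive (canonical action
set as key) with its score and provenance (search id, step, seed); batches
of searches derive per-search seeds from the master seed deterministically,
so results are independent of worker scheduling.

## Action space conventions

Constraints are declared as (source kind, target kind, locality) triples
over the kinds *gene*, *internal protein*, *membrane protein*, *external
input*, read directionally: a triple licenses sources of the first kind to
regulate targets of the second. AND-pair composites, when enabled, pair two
distinct same-cell species that are each individually licensed for the
target; pairs are capped at two members in search-generated terms (fixture
rules may carry larger frozen logic). Self-edges are off for search unless
a constraint enables them; bundled reference rules may contain
self-sustaining terms regardless. In multicellular problems every template
is tiled across all cells atomically, and templates with adjacent-cell
sources instantiate in both directions for every neighboring cell pair.

For the segment polarity problem this enumeration yields 448 candidate
templates. The original report counts 334 possible interactions; that
number is not derivable from its stated constraints (composite and
self-edge conventions are unspecified), so the fixture ships its
enumeration settings explicitly and logs the resulting count rather than
tuning to match. A *bidirectional* reading of the membrane/internal
constraint sentence would add membrane-to-internal actions (making, e.g.,
`SMO -| CIR` discoverable and raising the attainable reference overlap from
9 to 11 of the 15 discoverable edges, the published maximum); the
directional reading is kept because the constraint examples specify it.

## The segment polarity fixture

The bundled four-cell *Drosophila* segment polarity network follows the
Albert–Othmer Boolean formulation: per-cell species `wg, en, hh, ptc, ci`
(genes), `SLP, EN, CI, CIR, CIA` (internal proteins; `SLP` is an input
fixed by parasegment position), `WG, PTC, SMO, PH, HH` (membrane proteins),
on a ring of four cells. Re-encoded in dominant-inhibition form the listing
has **26** per-cell interaction templates, **11** of them prespecified as
prior knowledge — the five gene→protein activations, the three `wg`-rule
composites (`CIA&SLP`, `CIA&wg`, `SLP&wg`), `PTC` self-persistence, and the
two SMO frozen-clause companions (`HH@adj → SMO`, `PTC -| SMO`) — leaving
15 for the search to discover. Frozen clauses carry `SMO = ¬PTC ∨ HH@adj`,
`PTC = ptc ∨ (PTC ∧ ¬HH@adj)`, and `ci = TRUE ∧ ¬EN`. The
HH-mediated-removal literal inside the `PTC` clause is absorbed into the
persistence bookkeeping rather than listed as a separate edge.

Conditions are wild type plus `wg`, `hh`, `en` knockouts. Initial states
are the pre-pattern stripes of both transcripts and their proteins (`wg/WG`
posterior cell; `en/EN`, `hh/HH` anterior cell of the next parasegment;
`ptc/PTC`, `ci/CI` everywhere else; `SLP` in the posterior half), with the
knocked-out gene and protein zeroed per condition; reference attractors are
the fixture model's own simulated fixed points, making
self-consistency — the reference scoring 1.0 on every condition — the gate
for the transcription and simulator together. The wild-type fixed point is
the canonical striped pattern (single-cell `wg` and `en/hh` stripes, broad
`ci`/`PTC`, `CIR` confined to the interior cell). Where a re-encoding
choice was open, it was resolved once in favor of this self-consistency and
documented here; no choice was revisited against downstream scores.

## The synthetic-data generator

`random_model(n_species, n_interactions)` samples single-source
interactions (both signs, no self-edges) uniformly without replacement,
skipping opposite-sign contradictions. The default density is **one
interaction per species**: at that density the mean active fraction across
attractor representatives (64 random initial states per model) sits near
the one-third level that characterizes realistic expression snapshots,
which is the stated property of the validation models this generator
emulates; at twice the density inhibitory closure pushes most species
permanently off and the active fraction falls well below that
characteristic, so the denser default originally considered was rejected.
Density is a plain parameter for users who want other regimes.
`make_problem()` draws distinct random initial states (64 by default),
simulates the reference to build its census, and poses the recovery problem
with an empty base model and the full unconstrained action list.

What the generator does *not* emulate: measurement noise (references are
exact simulations), biased degree distributions, composite-heavy logic, or
multicellularity. Passing recovery tests therefore demonstrates that the
search recovers behavior and structure under clean conditions, not
robustness to noisy data.

## Problem sizes and numerical choices

The shipped studies are scaled to a single workstation: recovery runs use
20 independent searches on 8-species references, 64 initial states, 500
iterations per step, and at most 15 committed interactions; property suites
use up to 200 random models of up to 12 species, and mining checks use
alphabets of at most 12 edges where brute-force enumeration is feasible.
The full-scale campaigns this mirrors (thousands of searches, hundreds of
millions of simulated models, fifty-thousand-model cluster analyses) are
explicitly out of scope; the batch driver (`run_batch()`) provides the same
contract locally via forked workers.

Other fixed choices: simulation step cap 10,000 with a clear error (a guard
against malformed fixtures — deterministic synchronous dynamics otherwise
always halt within $2^n$ steps); perfect scores compared at tolerance
$10^{-9}$; archive keys are sorted action-id sets, equivalent to the
canonical serialization for search-generated models. The 2-D model-map
embedding is classical multidimensional scaling of the Jaccard distance
matrix — deterministic, metric-faithful for visualization, with cluster
labels taken from search provenance (or distance-threshold hierarchical
clustering when provenance is absent); prespecified edges are excluded from
clustering distances since all archived models share them by construction.

## Known limitations

* Synchronous updating only; asynchronous semantics would change both
  attractors and scores.
* The greedy edit distance can exceed the optimal transport cost on
  adversarial censuses; scores are comparable across models because every
  model is scored by the same procedure.
* Distinguishing-set mining reports minimal sets with identical support
  signatures; published counts of *all* qualifying itemsets are therefore
  not comparable quantities.
* The interaction-knockout semantics for rules backed by frozen clauses is
  a modelling decision (documented above), not a consequence of the
  dominant-inhibition algebra.
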