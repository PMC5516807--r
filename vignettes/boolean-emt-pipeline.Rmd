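---
title: "Boolean dynamics, stable motifs and the EMT phenotype spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean dynamics, stable motifs and the EMT phenotype spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolmotifs)
```

## The modelling framework

`boolmotifs` works with Boolean network models of signal transduction: each
molecular species (ligand, receptor, kinase, transcription factor,
microRNA, phenotype marker) is a node that is either ON (above-threshold
activity, logical 1) or OFF (below threshold, logical 0), and each node
carries an update rule — a Boolean expression over its regulators. This
coarse abstraction is appropriate when the relevant biology is switch-like
(a pathway is engaged or it is not) and kinetic parameters are unknown,
which is the usual situation for large signalling maps such as the network
driving the TGF&beta;-induced epithelial-to-mesenchymal transition (EMT).

Internally every rule is stored as a truth table over its *functional*
inputs: inputs without functional influence (e.g. `B` in `B & !B | C`) are
pruned at parse time. This makes rule evaluation, restriction under clamps,
prime-implicant computation and the interaction graph (an edge `u -> v`
exists iff flipping `u` can change `v`'s rule) exact, and it means the edge
count reported for a model reflects *interactions*, not lexical mentions.
Edge signs are derived only where the rule is monotone in that input;
non-monotone inputs are reported unsigned, because the rules — not a drawn
diagram — are the ground truth.

## Stochastic asynchronous dynamics and the EMT% readout

Biological cells do not update all their components in lockstep, so the
default update scheme is *random-order asynchronous*: in each round every
free (unclamped) node is updated once, in a fresh uniformly random
permutation, each update seeing the latest state. Fixed points of the rules
are absorbing under this and every other offered scheme (general
asynchronous, synchronous, and a rank-respecting variant whose rank map the
user supplies; the precise ranked ordering used elsewhere in the literature
is not fixed here, so it is exposed as configuration rather than guessed).

A simulation ensemble (`run_simulations()`) starts all runs from a chosen
initial state, stops a run early once it reaches a verified fixed point,
and flags — never drops — runs that fail to converge within the round
budget (default `max_rounds = 100`, comfortably above the settling time of
the cascades studied here). The headline readout is **EMT%**: the
percentage of runs whose final state has the EMT readout node ON. Because
update order is stochastic, EMT% is a property of the ensemble; every
stochastic stage takes an explicit seed and is bit-reproducible.

## Perturbations and combinatorial screens

A knockout clamps a node OFF, a constitutive activation clamps it ON; in
both cases the node's rule is ignored for the duration and the clamp is
applied from the initial state onward. The screen machinery
(`build_pool()`, `run_screen()`, `run_ca_screen()`) evaluates every
combination of clamps at a given order with an identical, seeded simulation
configuration and classifies combinations with EMT% = 0 across all runs as
*blockers*.

Pool construction mirrors standard screen hygiene: the driving signal, its
receptor, the phenotype marker and the readout node are never perturbed
(they force the readout trivially); nodes whose single knockout blocks are
excluded from pairs; and for orders three and four the default
`"partner_removal"` rule removes every node that appears in a fully
blocking pair *except* the node common to all such pairs, keeping the
shared hub eligible. This last rule is genuinely a design choice — it is
the only pool rule consistent with published screen tables of this kind,
and it is configurable (`pool_rule = "pairs_only"`) precisely because the
underlying convention is a reporting convention, not a mathematical
necessity. "Partial suppression" similarly has no canonical threshold; the
default flags EMT% below 50 and is configurable.

## Stable motifs

The central structural concept is the **stable motif**: a set of nodes and
node states forming a self-sustaining generalized positive feedback loop.
Once the network enters a motif's partial state it can never leave it, so
motifs are points of no return that lock in cell-fate decisions.

The package characterises motifs through prime implicants. A partial
assignment is self-sustaining exactly when, for every assigned node-state
`n = s`, every prime implicant of `rule(n) == 1-s` contains a literal
contradicted by the assignment — the rule can never fire against the
motif. Stable motifs are the *inclusion-minimal* nonempty consistent
assignments closed under this condition (equivalently, the network's
minimal trap spaces) whose support induces a strongly connected subgraph of
the interaction graph; the strong-connectivity requirement separates
genuine feedback cores from their downstream percolation tails.
`find_stable_motifs()` performs a complete branch-and-close search: every
node-state seeds an assignment, and each unblocked opposite implicant
branches over the literals that could block it. We deliberately do *not*
take strongly connected components of the expanded network at face value:
SCCs are maximal objects, so overlapping feedback loops would collapse into
one oversized motif, and a self-sustaining core embedded inside a larger
inconsistent component would be missed. The expanded network itself
(`build_expanded()`: ON/OFF virtual nodes plus composite nodes per
conjunctive implicant) is retained as the structural view of the same
implicant data. Prime implicants are computed by Quine–McCluskey complete
prime enumeration with a 16-input budget per rule — signalling rules are
small-arity, so this is not restrictive in practice.

Every reported motif is verified as a partial fixed point, and the test
suite additionally checks motif sets against an independent brute-force
oracle (exhaustive partial-assignment enumeration) on dozens of generated
networks, and checks the trap property by mass simulation.

## Succession diagrams, attractors and the approximate mode

Fixing a motif and substituting its states into the remaining rules (with
iterated constant propagation) yields a reduced network; recursing produces
the **succession diagram**, a DAG of motif stabilization sequences whose
sinks carry attractors. Reduced networks reached by different motif
orderings are shared by memoizing on the fixed assignment. At a sink,
either all nodes are fixed (a steady state, verified against every rule),
or free nodes remain with no motif: the leftover network's attractors are
then enumerated exhaustively from its general-asynchronous state-transition
graph when it has at most `max_exact = 16` free nodes. Beyond that budget
the package switches to an explicitly flagged *approximate* mode (long
stochastic simulation from random states), mirroring the practice of
flagging rather than hiding approximations; nothing in this package's
shipped analyses triggers it. Complex (oscillatory) attractors are
reported as such and excluded from steady-state tables with a count.

One caveat inherited from network reduction: constant propagation
preserves steady states exactly but can in principle alter the fine
structure of complex attractors in pathological cases. The oracle
comparison tests on random networks are the guard rail.

## Stable-motif control

A **control set** is a set of node-state interventions whose *transient*
enforcement drives every initial state to a target attractor — a
corrective intervention, in contrast to the preventive screen. Control
sets are read off the succession diagram: each motif sequence whose sink
carries exactly the target contributes the union of its motif node-states
as a candidate, and `derive_control_sets()` extracts all minimal
sufficient subsets by *logical-closure certification*: clamping the subset
and propagating constants must fix the entire network in the target state.
The certificate is sufficient by construction (after release the target is
a fixed point of the free rules), sidesteps simulation noise during
derivation, and the full candidate always certifies, so the search is
well-founded. Dynamic verification is kept strictly separate:
`verify_control()` clamps the interventions, simulates until a
trajectory's state has been unchanged for `release_stable_rounds = 3`
consecutive rounds (the motif sequence has locked in), releases the
clamps, runs the free dynamics to a fixed point, and reports the fraction
of initial states that end in the target — exhaustively over all `2^n`
initial states for the network sizes used here. The release-after-stability
rule implements "transient" concretely; three quiet rounds is a
conservative default for cascades of this depth and is configurable.

## The epithelial/mesenchymal plane, PCA and clustering

To place steady states on the epithelial–mesenchymal spectrum, states are
spin-encoded (OFF &rarr; &minus;1, ON &rarr; +1) and projected onto the
plane spanned by the two reference patterns using the biorthogonal
dual-pattern construction from associative-memory theory: with overlap
matrix `A[mu,nu] = mean(xi_mu * xi_nu)` and raw overlaps
`m[nu] = mean(xi_nu * sigma)`, the coordinates are `a = solve(A, m)`. This
is the unique linear scheme sending the epithelial reference to
`(a_M, a_E) = (0, 1)` and the mesenchymal reference to `(1, 0)` exactly,
for any distinct reference pair. States are labelled epithelial-like when
`a_E - a_M > 0.65`, mesenchymal-like when `a_M - a_E > 0.65`, and
hybrid-like strictly in between; the boundary value itself goes to the
non-hybrid class (the hybrid inequalities are strict), with a `1e-9`
tolerance so that rational boundary coordinates are not misassigned by
floating-point solve. For states that agree with one reference on every
shared node and split the differing nodes with fraction `f` epithelial,
the coordinates obey the closed form `a_E = f`, `a_M = 1 - f` — a
hand-checkable invariant the tests exercise.

PCA (`run_pca()`) uses mean-centered, unscaled spins by default (a 0/1
encoding is offered; spins make the two phenotype poles symmetric around
the origin, which is why they are the default). Because principal
component signs are arbitrary, the convention is fixed deterministically:
PC1 so that the mesenchymal reference scores negative, other components by
making the largest-magnitude loading positive. Hierarchical clustering
(`run_hclust()`) uses Hamming distance — the natural metric for Boolean
states — with average linkage, both configurable, and a flat cut at
`k = 3` for the epithelial/hybrid/mesenchymal macro-groups.

## The synthetic generator and the packaged demonstration model

The generator (`generate_toy()`) emits networks in which a requested
partial state is planted as a sign-consistent feedback cycle — making the
assignment and its complement stable motifs by construction — while the
remaining nodes receive random truth tables over randomly drawn inputs.
Every emitted network ships with brute-force ground truth (exhaustive
fixed-point scan; terminal SCCs of the general-asynchronous transition
graph; exhaustive minimal-partial-fixed-point motifs), so each pipeline
stage is tested against an independent oracle. Generated networks are
capped at 16 nodes (10 for motif oracles) to keep the oracles exhaustive.

The packaged demonstration model (`emt_example_network()`, 10 nodes) is a
*synthetic* miniature of TGF&beta;-driven EMT, authored for this package:
the signal activates a canonical (SMAD) and a non-canonical (RAS/MEK) arm
converging on E-cadherin-repressing transcription factors (SNAI1, ZEB),
ZEB and miR200 mutually inhibit, SNAI1 feeds back on RAS so the
mesenchymal programme self-sustains, and an EMT readout reports E-cadherin
loss. Its architecture reproduces the qualitative phenomenology that
motivates the pipeline — the driven model completes EMT from the
epithelial state; only the direct marker repressors block as single
knockouts; the effective pairs all include SMAD; miR200 activation is the
unique single-node activating blocker; single-factor knockouts leave
hybrid states with mesenchymal signalling but epithelial markers; and an
all-OFF stable motif spanning the signalling feedback loop (30% of nodes)
stabilizes the epithelial state once the signal is absent. One designed
deviation from the large-network picture: ZEB blocks EMT from *downstream*
of the epithelial motif, so the structural consistency between blockers
and control sets holds for the signalling-layer interventions but not for
ZEB — a reminder that a 10-node miniature compresses, rather than
reproduces, a 69-node map.

What the passing tests show, and what they do not: they show the
implementation is correct against exhaustive oracles on networks small
enough to enumerate, and that the pipeline's qualitative behaviour on the
demonstration model matches its designed ground truth. They do not show
anything about any particular published biological model, whose rule set
is not distributed with this package; conclusions about real EMT biology
require running the pipeline on a curated model of that biology.

## Numerical choices and problem sizes

* Rules: at most 16 inputs each (Quine–McCluskey budget); parse errors name
  the offending line.
* Simulation: `n_runs = 1000` is the screen-scale default; the test suite
  and worked examples use 50–200 runs, which is ample for a model whose
  driven dynamics are deterministic in outcome, and keeps the default test
  run around half a minute.
* Exhaustive stages: attractor oracles to `2^16` states; motif oracles to
  `3^10` partial assignments; control verification to `2^12` initial
  states in the shipped analyses.
* Mass verification sweeps share one update permutation per round across
  trajectories (each row still follows a valid random-order trajectory);
  per-run independent permutations are used wherever inter-run variability
  is the quantity of interest.
* Ties, boundaries, degeneracies: boundary plane coordinates go to the
  non-hybrid class; PCA on an all-identical table errors; identical
  reference patterns error; clamping an unknown node errors.

## Known limitations

* No continuous-time or probabilistic-Boolean semantics; no rule learning.
* Approximate attractor mode trades completeness for tractability and is
  always flagged; it is untriggered in shipped analyses.
* Control derivation certifies sufficiency by logical closure. The full
  motif-sequence union always certifies, so derivation never comes back
  empty for a reachable steady target, but an intervention subset that is
  sufficient only through dynamic timing effects (without a closure
  certificate) is not enumerated; `verify_control()` can assess any such
  candidate supplied by hand.
* The motif search is exponential in the worst case; it is intended for
  the tens-of-nodes regime typical of curated signalling models, not for
  thousand-node networks.
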