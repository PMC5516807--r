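# boolmotifs

Stable-motif analysis, attractor control and phenotype landscapes for
Boolean networks, built around the question that motivates systems-level
studies of the epithelial-to-mesenchymal transition (EMT): **which single
or combined interventions stop a signal-driven cell-fate transition, why do
they work, and what intermediate (hybrid) phenotypes do the failed ones
leave behind?**

## Who this is for

Systems biologists working with logical (Boolean) models of signalling —
each node ON/OFF with an update rule over its regulators — who want, in
one package:

* **Stochastic asynchronous simulation** with the EMT% readout: the
  percentage of runs whose readout node (e.g. `EMT`) ends ON, under
  random-order asynchronous updating (also general-asynchronous,
  synchronous and ranked schemes), fully seeded and reproducible.
* **Combinatorial perturbation screens**: knockouts (clamp OFF) and
  constitutive activations (clamp ON) of up to four nodes, with the
  standard pool-exclusion rules, identifying *blockers* (EMT% = 0).
* **Stable motifs**: self-sustaining generalized positive feedback loops —
  inclusion-minimal consistent assignments closed under prime-implicant
  blocking (minimal trap spaces) with strongly connected support — found by
  a complete branch-and-close search; plus the expanded-network view.
* **Succession diagrams and attractors**: recursive motif
  fixation/reduction with memoization; sinks carry attractors; complex
  attractors are detected and flagged; exhaustive leftover enumeration up
  to 16 free nodes, with an explicitly flagged approximate mode beyond.
* **Stable-motif control sets**: minimal node-state interventions whose
  *transient* enforcement drives every initial state to a target attractor,
  derived from the succession diagram by logical-closure certification and
  verified dynamically (`verify_control()`), exhaustively over all `2^n`
  initial states on shipped analyses.
* **The E/M phenotype plane**: biorthogonal projection of steady states
  onto epithelial/mesenchymal reference patterns — spin-encode states,
  compute overlaps `m`, solve `a = A^{-1} m` so the references land exactly
  at `(a_M, a_E) = (0, 1)` and `(1, 0)` — with the 0.65 threshold
  classification (epithelial-like / hybrid-like / mesenchymal-like), PCA
  with deterministic sign conventions, and Hamming/average-linkage
  hierarchical clustering.
* **Synthetic ground truth**: a generator that plants verified stable
  motifs in random networks, plus brute-force oracles (exhaustive
  fixed-point scan, state-transition-graph attractors, exhaustive motif
  enumeration) so every stage is testable end to end.

A 10-node *synthetic* EMT-like demonstration model ships with the package
(`emt_example_network()`); it is authored for this package, not a
transcription of any published model.

## Worked example

```r
library(boolmotifs)

net <- emt_example_network()
net
#> boolean_network: 10 nodes, 14 interaction edges

st <- emt_example_states()            # signal-free epithelial & mesenchymal
driven <- apply_perturbation(net, c(TGFb = 1))

run_simulations(driven, st$epithelial, sim_config(n_runs = 200, seed = 1))
#> sim_outcome: 200 runs, 100% with EMT ON, 0 non-convergent
```

The driving signal converts every run of the epithelial state to EMT.
Screening knockouts (order 1, then pairs of the non-blocking nodes):

```r
res <- run_screen_pipeline(list(seed = 1, n_runs = 200, orders = 1:2))
res$table
#>   order pool_size n_combinations n_blockers
#> 1     1         6              6          2
#> 2     2         4              6          2
res$blockers[["2"]]
#> [1] "SMAD+RAS" "SMAD+MEK"
```

Only the two direct marker repressors (`SNAI1`, `ZEB`) block alone; every
effective pair contains `SMAD` — canonical-arm inhibition must be combined
with a hit on the non-canonical arm. Control sets for the epithelial state
(corrective rather than preventive interventions):

```r
cs <- derive_control_sets(net, st$epithelial)
cs
#> control_set: TGFb=0, RAS=0
#> control_set: TGFb=0, MEK=0
#> control_set: TGFb=0, SNAI1=0
verify_control(net, cs[[1]])
#> [1] 1
#> attr(,"n")
#> [1] 1024
```

Each set removes the signal and silences one node of the self-sustaining
mesenchymal feedback loop, and transient enforcement drives **all 1024**
initial states to the epithelial steady state. Finally, the steady-state
landscape across all single-node perturbations of the driven network:

```r
land <- run_landscape_pipeline(list(seed = 1))
land$summary
#>              label Freq
#> 1  epithelial-like    2
#> 2      hybrid-like    5
#> 3 mesenchymal-like   15
subset(land$landscape,
       perturbation %in% c("unperturbed", "SNAI1=0", "reference_epithelial"))[, 1:4]
#>            perturbation        a_M        a_E            label
#> 1           unperturbed  0.0000000 -1.0000000 mesenchymal-like
#> 11              SNAI1=0 -0.7142857 -0.2857143      hybrid-like
#> 21 reference_epithelial  0.0000000  1.0000000  epithelial-like
```

The unperturbed driven network is mesenchymal-like; knocking out a single
transcription factor (`SNAI1=0`) does **not** restore the epithelial
reference but leaves a hybrid state — epithelial markers ON with the
signalling arm still mesenchymal — which is the central reason combined
interventions matter. The reference states project exactly to `(0, 1)` and
`(1, 0)`.

See the vignette (`vignettes/boolean-emt-pipeline.Rmd`) for the model
assumptions, parameter meanings and design choices.

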