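test_that("the expanded network has the expected virtual and composite structure", {
  # self-activation: both virtual nodes carry self-loops
  ex <- build_expanded(parse_boolean_network("A, A"))
  el <- igraph::as_data_frame(ex$graph)
  expect_true(any(el$from == "A=1" & el$to == "A=1"))
  expect_true(any(el$from == "A=0" & el$to == "A=0"))
  # single conjunctive implicant: one composite fed by both literals
  ex2 <- build_expanded(parse_boolean_network(c("A, B & C", "B, B", "C, C")))
  expect_length(ex2$composite, 1)   # B&C feeds A=1; A=0 gets two single-literal edges
  cid <- names(ex2$composite)[vapply(ex2$composite, function(x)
    setequal(x, c("B=1", "C=1")), logical(1))]
  expect_length(cid, 1)
  el2 <- igraph::as_data_frame(ex2$graph)
  expect_true(any(el2$from == cid & el2$to == "A=1"))
  expect_setequal(el2$from[el2$to == cid], c("B=1", "C=1"))
})

test_that("stable motifs of canonical small circuits are exact", {
  expect_setequal(motif_keys(find_stable_motifs(mutual_net())),
                  c("A=0,B=0", "A=1,B=1"))
  expect_setequal(motif_keys(find_stable_motifs(toggle_net())),
                  c("A=0,B=1", "A=1,B=0"))
  expect_setequal(motif_keys(find_stable_motifs(parse_boolean_network("A, A"))),
                  c("A=0", "A=1"))
  # acyclic network: no feedback, no motifs
  expect_length(find_stable_motifs(chain_net()), 0)
  # negative loop alone cannot sustain a partial fixed point
  expect_length(find_stable_motifs(oscillator_net()), 0)
})

test_that("overlapping feedback loops yield their minimal self-sustaining cores", {
  # the ON state can be sustained through either loop (A-B or A-C), giving
  # two minimal motifs; the OFF state needs both branches silenced at once
  net <- parse_boolean_network(c("A, B | C", "B, A", "C, A"))
  ks <- motif_keys(find_stable_motifs(net))
  expect_setequal(ks, c("A=0,B=0,C=0", "A=1,B=1", "A=1,C=1"))
  expect_identical(ks, motif_keys(brute_force_motifs(net)))
  # downstream AND target stays outside the component
  net2 <- parse_boolean_network(c("A, B", "B, A", "C, A & B"))
  expect_setequal(motif_keys(find_stable_motifs(net2)),
                  c("A=0,B=0", "A=1,B=1"))
  expect_identical(motif_keys(find_stable_motifs(net2)),
                   motif_keys(brute_force_motifs(net2)))
})

test_that("expanded-network motifs equal the brute-force oracle on random toys", {
  for (s in 1:6) {
    toy <- generate_toy(toy_spec(7, planted_motif = c(X = 1L, Y = 1L),
                                 rng_seed = s))
    expect_identical(motif_keys(find_stable_motifs(toy$net)),
                     motif_keys(toy$ground_truth$motifs),
                     label = sprintf("motifs, toy seed %d", s))
  }
})

test_that("network reduction substitutes constants and simplifies", {
  net <- parse_boolean_network(c("A, A", "B, A & C", "C, C"))
  red <- reduce_network(net, c(A = 1L))
  expect_identical(red$rules[["B"]]$inputs, "C")
  expect_false("A" %in% red$nodes)
  expect_equal(attr(red, "fixed")[["A"]], 1L)
  # fixing A = 0 propagates B = 0
  red0 <- reduce_network(net, c(A = 0L))
  expect_equal(attr(red0, "fixed")[["B"]], 0L)
  expect_false("B" %in% red0$nodes)
  expect_error(reduce_network(net, c(B = 1L)), "not a partial fixed point")
})

test_that("a reduced network never re-yields the motif it was reduced by", {
  net <- emt_example_network()
  for (m in find_stable_motifs(net)) {
    red <- reduce_network(net, m)
    for (m2 in find_stable_motifs(red))
      expect_false(any(names(m2) %in% names(m)))
  }
})

test_that("succession diagrams terminate in the exact attractor set", {
  # two independent toggle switches: 4 steady states
  d <- build_succession_diagram(double_toggle_net())
  atts <- find_attractors(double_toggle_net(), diagram = d)
  expect_length(atts, 4)
  expect_identical(attractor_keys(atts),
                   attractor_keys(brute_force_attractors(double_toggle_net())))
  # single global fixed point
  atts1 <- find_attractors(chain_net())
  expect_length(atts1, 1)
  expect_equal(unname(atts1[[1]]$states[1, ]), c(0L, 0L, 0L))
  # negative feedback loop: one complex attractor, flagged as such
  attsc <- find_attractors(oscillator_net())
  expect_length(attsc, 1)
  expect_identical(attsc[[1]]$kind, "complex")
  expect_identical(attractor_keys(attsc),
                   attractor_keys(brute_force_attractors(oscillator_net())))
})

test_that("succession-diagram attractors equal the STG oracle on random toys", {
  for (s in c(2, 5, 8, 13)) {
    toy <- generate_toy(toy_spec(7, planted_motif = c(X = 1L, Y = 0L),
                                 rng_seed = s))
    expect_identical(attractor_keys(find_attractors(toy$net)),
                     attractor_keys(toy$ground_truth$attractors),
                     label = sprintf("attractors, toy seed %d", s))
  }
})

test_that("motif partial states are trapping for simulated trajectories", {
  net <- emt_example_network()
  motifs <- find_stable_motifs(net)
  expect_gt(length(motifs), 0)
  set.seed(42)
  for (m in motifs) {
    free <- setdiff(net$nodes, names(m))
    init <- matrix(sample(0:1, 500 * length(free), replace = TRUE),
                   nrow = 500, dimnames = list(NULL, free))
    states <- cbind(init, matrix(m, nrow = 500, ncol = length(m),
                                 byrow = TRUE,
                                 dimnames = list(NULL, names(m))))[, net$nodes]
    for (round in 1:10) {
      states <- boolmotifs:::simulate_matrix(net, states, 1L)
      expect_true(all(states[, names(m)] ==
                        matrix(m, 500, length(m), byrow = TRUE)),
                  label = sprintf("motif %s trapped at round %d",
                                  paste(names(m), collapse = "+"), round))
    }
  }
})

test_that("every diagram sink steady state satisfies all rules exactly", {
  nets <- list(emt_example_network(), demo_driven(), double_toggle_net())
  for (net in nets)
    for (a in find_attractors(net))
      if (a$kind == "steady_state")
        expect_true(is_fixed_point(net,
          stats::setNames(a$states[1, ], colnames(a$states))))
})

test_that("the driven demo network reduces to a single mesenchymal sink", {
  d <- build_succession_diagram(demo_driven())
  atts <- find_attractors(demo_driven(), diagram = d)
  expect_length(atts, 1)
  s <- stats::setNames(atts[[1]]$states[1, ], colnames(atts[[1]]$states))
  expect_equal(s[["EMT"]], 1L)
  expect_equal(s[["Ecadherin"]], 0L)
})
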