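make_refs <- function(n_common, n_diff, seed = 1) {
  # epithelial/mesenchymal spin patterns agreeing on n_common nodes
  set.seed(seed)
  nodes <- sprintf("g%d", seq_len(n_common + n_diff))
  epi <- stats::setNames(sample(0:1, n_common + n_diff, replace = TRUE), nodes)
  mes <- epi
  mes[seq_len(n_diff)] <- 1L - mes[seq_len(n_diff)]
  list(epi = epi, mes = mes,
       refs = reference_patterns(epi, mes), diff = nodes[seq_len(n_diff)])
}

test_that("reference states project to (0,1) and (1,0) exactly", {
  for (seed in 1:5) {
    w <- make_refs(n_common = 3, n_diff = 7, seed = seed)
    pe <- project_state(w$refs, w$epi)
    pm <- project_state(w$refs, w$mes)
    expect_equal(c(pe$a_M, pe$a_E), c(0, 1), tolerance = 1e-12)
    expect_equal(c(pm$a_M, pm$a_E), c(1, 0), tolerance = 1e-12)
    expect_identical(pe$label, "epithelial-like")
    expect_identical(pm$label, "mesenchymal-like")
  }
})

test_that("mosaic states follow the closed form in the match fraction", {
  # state = epithelial on a fraction f of the differing nodes, mesenchymal on
  # the rest: (a_E, a_M) = ((1+x)/2, (1-x)/2) with x = 2f - 1, independent of
  # how many nodes the references share
  for (n_common in c(2, 6)) {
    w <- make_refs(n_common = n_common, n_diff = 8, seed = 3)
    for (k in 0:8) {
      s <- w$mes
      s[w$diff[seq_len(k)]] <- w$epi[w$diff[seq_len(k)]]
      p <- project_state(w$refs, s)
      x <- 2 * (k / 8) - 1
      expect_equal(p$a_E, (1 + x) / 2, tolerance = 1e-12)
      expect_equal(p$a_M, (1 - x) / 2, tolerance = 1e-12)
    }
  }
  # half/half split lands exactly on the diagonal midpoint: hybrid
  w <- make_refs(n_common = 4, n_diff = 6, seed = 9)
  s <- w$mes
  s[w$diff[1:3]] <- w$epi[w$diff[1:3]]
  p <- project_state(w$refs, s)
  expect_equal(p$a_E - p$a_M, 0, tolerance = 1e-12)
  expect_identical(p$label, "hybrid-like")
})

test_that("projection is invariant to node ordering", {
  w <- make_refs(3, 7, seed = 2)
  s <- w$mes
  s[w$diff[1:2]] <- w$epi[w$diff[1:2]]
  p1 <- project_state(w$refs, s)
  p2 <- project_state(w$refs, s[sample(names(s))])
  expect_equal(p1$a_E, p2$a_E)
  expect_equal(p1$a_M, p2$a_M)
})

test_that("boundary coordinates go to the non-hybrid class", {
  # 40 differing nodes, 33 epithelial-matching: a_E - a_M = 0.65 exactly
  w <- make_refs(n_common = 10, n_diff = 40, seed = 4)
  s <- w$mes
  s[w$diff[1:33]] <- w$epi[w$diff[1:33]]
  p <- project_state(w$refs, s)
  expect_equal(p$a_E - p$a_M, 0.65, tolerance = 1e-9)
  expect_identical(p$label, "epithelial-like")
  s2 <- w$epi
  s2[w$diff[1:33]] <- w$mes[w$diff[1:33]]
  expect_identical(project_state(w$refs, s2)$label, "mesenchymal-like")
})

test_that("projection rejects mismatched node sets and identical references", {
  w <- make_refs(3, 7)
  bad <- w$epi[-1]
  expect_error(project_state(w$refs, bad), "node")
  expect_error(reference_patterns(w$epi, w$epi), "distinct")
})

test_that("steady-state collection covers every single-node perturbation", {
  tab <- collect_steady_states(demo_driven())
  expect_s3_class(tab, "steady_state_table")
  expect_equal(tab$n_complex, 0)
  labs <- unique(tab$perturbation)
  expect_true("unperturbed" %in% labs)
  # 9 perturbable nodes (TGFb is clamped), knockout and activation each
  expect_length(labs, 1 + 2 * 9)
  expect_false(any(is.na(tab$states)))
})

test_that("landscape labels place the designed perturbations on the spectrum", {
  net <- emt_example_network()
  st <- emt_example_states()
  refs <- reference_patterns(st$epithelial, st$mesenchymal)
  tab <- collect_steady_states(demo_driven(net))
  land <- classify_landscape(tab, refs)
  # the unperturbed driven network completes the transition
  expect_identical(land$label[land$perturbation == "unperturbed"],
                   "mesenchymal-like")
  # knocking out a single E-cadherin-repressing factor leaves a mixed state:
  # epithelial markers restored, signalling arm still mesenchymal
  expect_identical(land$label[land$perturbation == "SNAI1=0"], "hybrid-like")
  expect_identical(land$label[land$perturbation == "miR200=1"], "hybrid-like")
})

test_that("PCA separates antipodal states and fixes deterministic signs", {
  nodes <- sprintf("g%d", 1:8)
  epi <- stats::setNames(rep(0L, 8), nodes); epi[1:2] <- 1L
  mes <- stats::setNames(1L - epi, nodes)
  mes[8] <- epi[8]   # references must share at least one node state
  refs <- reference_patterns(epi, mes)
  tab <- structure(list(
    states = rbind(epi, mes, epi, mes), perturbation = letters[1:4],
    n_complex = 0L, approximate = FALSE), class = "steady_state_table")
  p <- run_pca(tab, refs)
  expect_lt(p$scores[2, 1], 0)             # mesenchymal scores negative on PC1
  expect_gt(p$scores[1, 1], 0)
  expect_equal(p$sdev[2], 0, tolerance = 1e-12)   # only one direction varies
  p2 <- run_pca(tab, refs)
  expect_identical(p$scores, p2$scores)
  expect_error(run_pca(structure(list(states = rbind(epi, epi, epi)),
                                 class = "steady_state_table"), refs),
               "degenerate")
})

test_that("PC1 ordering and plane labels agree on a separated landscape", {
  # construct a table with clear epithelial / mid-hybrid / mesenchymal groups
  w <- make_refs(n_common = 2, n_diff = 10, seed = 6)
  states <- list()
  for (k in c(0, 1, 5, 9, 10)) {
    s <- w$mes
    if (k > 0) s[w$diff[seq_len(k)]] <- w$epi[w$diff[seq_len(k)]]
    states[[length(states) + 1]] <- s
  }
  tab <- structure(list(states = do.call(rbind, states),
                        perturbation = sprintf("s%d", 1:5),
                        n_complex = 0L, approximate = FALSE),
                   class = "steady_state_table")
  land <- classify_landscape(tab, w$refs)
  expect_identical(land$label, c("mesenchymal-like", "mesenchymal-like",
                                 "hybrid-like", "epithelial-like",
                                 "epithelial-like"))
  p <- run_pca(tab, w$refs)
  # three-way grouping by PC1 sign/magnitude matches the threshold labels
  pc1 <- p$scores[, 1]
  expect_true(all(pc1[land$label == "mesenchymal-like"] <
                    pc1[land$label == "hybrid-like"]))
  expect_true(all(pc1[land$label == "hybrid-like"] <
                    pc1[land$label == "epithelial-like"]))
  hc <- run_hclust(tab, k = 3)
  expect_equal(length(unique(hc$clusters[land$label == "mesenchymal-like"])), 1)
  expect_equal(length(unique(hc$clusters[land$label == "epithelial-like"])), 1)
  # adjusted agreement of the two three-way splits is perfect here
  expect_equal(length(unique(paste(hc$clusters, land$label))), 3)
})

test_that("hierarchical clustering merges duplicates first and references last", {
  net <- emt_example_network()
  st <- emt_example_states()
  states <- rbind(st$epithelial[net$nodes], st$epithelial[net$nodes],
                  st$mesenchymal[net$nodes])
  rownames(states) <- c("e1", "e2", "m")
  tab <- structure(list(states = states, perturbation = c("e1", "e2", "m"),
                        n_complex = 0L, approximate = FALSE),
                   class = "steady_state_table")
  hc <- run_hclust(tab, k = 2)
  expect_equal(hc$tree$height[1], 0)                  # identical pair merges at 0
  d <- as.matrix(stats::dist(states, method = "manhattan") / ncol(states))
  expect_equal(max(hc$tree$height), max(d))           # references merge last
  expect_identical(hc$clusters[["e1"]], hc$clusters[["e2"]])
})
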