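test_that("combination counts are exact binomial coefficients", {
  expect_identical(screen_combination_count(65, 1), 65)
  expect_identical(screen_combination_count(58, 2), 1653)
  expect_identical(screen_combination_count(52, 3), 22100)
  expect_identical(screen_combination_count(52, 4), 270725)
})

test_that("candidate pools apply the exclusion rules order by order", {
  net <- emt_example_network()
  excl <- emt_example_exclusions()
  p1 <- build_pool(net, 1, excl)
  expect_setequal(p1$pool, c("SMAD", "RAS", "MEK", "SNAI1", "ZEB", "miR200"))
  expect_equal(p1$n_combinations, 6)
  p2 <- build_pool(net, 2, excl, single_blockers = c("SNAI1", "ZEB"))
  expect_setequal(p2$pool, c("SMAD", "RAS", "MEK", "miR200"))
  expect_equal(p2$n_combinations, choose(4, 2))
  # partner removal keeps the node common to all blocking pairs
  p3 <- build_pool(net, 3, excl, single_blockers = c("SNAI1", "ZEB"),
                   pair_blockers = list(c("SMAD", "RAS"), c("SMAD", "MEK")))
  expect_setequal(p3$pool, c("SMAD", "miR200"))
  expect_equal(p3$n_combinations, 0)
  p3b <- build_pool(net, 3, excl, single_blockers = c("SNAI1", "ZEB"),
                    pair_blockers = list(c("SMAD", "RAS"), c("SMAD", "MEK")),
                    pool_rule = "pairs_only")
  expect_setequal(p3b$pool, c("SMAD", "RAS", "MEK", "miR200"))
  expect_error(build_pool(net, 5, excl), "order")
  expect_error(build_pool(net, 1, "NOPE"), "not in network")
})

test_that("the knockout screen recovers the designed blockers", {
  net <- emt_example_network()
  driven <- demo_driven(net)
  st <- emt_example_states()
  cfg <- sim_config(n_runs = 100, seed = 17)
  s1 <- run_screen(driven, build_pool(net, 1, emt_example_exclusions()),
                   st$epithelial, cfg)
  expect_setequal(s1$blockers, c("SNAI1", "ZEB"))
  s2 <- run_screen(driven,
                   build_pool(net, 2, emt_example_exclusions(),
                              single_blockers = s1$blockers),
                   st$epithelial, cfg)
  expect_setequal(s2$blockers, c("SMAD+RAS", "SMAD+MEK"))
  expect_true(all(grepl("SMAD", s2$blockers)))
  expect_equal(nrow(s2$results), 6)
})

test_that("blocker sets are invariant to the RNG seed", {
  net <- emt_example_network()
  driven <- demo_driven(net)
  st <- emt_example_states()
  plan <- build_pool(net, 1, emt_example_exclusions())
  blocks <- lapply(c(1, 99, 2026), function(seed)
    sort(run_screen(driven, plan, st$epithelial,
                    sim_config(n_runs = 100, seed = seed))$blockers))
  expect_identical(blocks[[1]], blocks[[2]])
  expect_identical(blocks[[2]], blocks[[3]])
})

test_that("adding a blocking single to any combination keeps EMT% at zero", {
  net <- emt_example_network()
  st <- emt_example_states()
  for (extra in list(c("SMAD", "miR200"), c("RAS", "MEK"), "miR200")) {
    clamps <- stats::setNames(rep(0L, length(extra) + 1), c("SNAI1", extra))
    pnet <- apply_perturbation(demo_driven(net), clamps)
    out <- run_simulations(pnet, st$epithelial, sim_config(n_runs = 50, seed = 3))
    expect_equal(out$emt_percentage, 0)
  }
})

test_that("the constitutive-activation screens find the miR200 blocker and no mixed pairs", {
  net <- emt_example_network()
  driven <- demo_driven(net)
  st <- emt_example_states()
  cfg <- sim_config(n_runs = 100, seed = 5)
  plan <- build_pool(net, 1, emt_example_exclusions())
  ca1 <- run_ca_screen(driven, plan, st$epithelial, cfg)
  expect_identical(ca1$blockers, "miR200")
  plan2 <- build_pool(net, 2, emt_example_exclusions(),
                      single_blockers = c("SNAI1", "ZEB"))
  mixed <- run_ca_screen(driven, plan2, st$epithelial, cfg, order = 2,
                         single_blocking_perturbations = "miR200=1")
  # in this synthetic model no mixed pair adds a new blocker; pairs
  # containing the individually blocking miR200=1 are excluded up front
  expect_length(mixed$blockers, 0)
  expect_false(any(grepl("miR200=1", mixed$results$clamps)))
  expect_true(all(grepl("=1", mixed$results$clamps)))
})

test_that("activating a node that is already ON leaves EMT% unchanged", {
  net <- emt_example_network()
  st <- emt_example_states()
  base <- run_simulations(demo_driven(net), st$epithelial,
                          sim_config(n_runs = 50, seed = 11))
  # TGFbR is ON in every reachable state of the driven network
  ca <- run_simulations(apply_perturbation(demo_driven(net), c(TGFbR = 1L)),
                        st$epithelial, sim_config(n_runs = 50, seed = 11))
  expect_equal(ca$emt_percentage, base$emt_percentage)
})
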