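#' Stable-motif control sets
#'
#' A control set is a set of node-state interventions whose *transient*
#' enforcement drives every initial condition of the network to a chosen
#' target attractor. Control sets are read off the succession diagram: each
#' motif sequence that leads exclusively to the target contributes the union
#' of its motif node-states as a candidate, and minimal sufficient subsets
#' are extracted by logical-closure certification (clamping the subset and
#' propagating constants must fix the entire network in the target state,
#' which also guarantees stability after release).
#'
#' @name motif_control
NULL

target_state_of <- function(target, nodes) {
  if (inherits(target, "attractor")) {
    if (target$kind != "steady_state")
      stop("control-set derivation targets steady-state attractors only")
    target <- stats::setNames(target$states[1, ], colnames(target$states))
  }
  stats::setNames(as.integer(target[nodes]), nodes)
}

closure_certifies <- function(net, interventions, target) {
  pr <- propagate_constants(apply_perturbation(net, interventions))
  length(pr$net$nodes) == 0L &&
    identical(unname(pr$fixed[names(target)]), unname(target))
}

minimal_certified_subsets <- function(net, candidate, target) {
  k <- length(candidate)
  if (k == 0L) return(list())
  found <- list()
  for (sz in seq_len(k)) {
    for (idx in utils::combn(k, sz, simplify = FALSE)) {
      sub <- candidate[idx]
      if (any(vapply(found, function(f)
        all(names(f) %in% names(sub)) && all(sub[names(f)] == f),
        logical(1)))) next                       # superset of a minimal set
      if (closure_certifies(net, sub, target))
        found[[length(found) + 1L]] <- sub
    }
    if (length(found) && sz >= max(lengths(found)) + 2L) break
  }
  found
}

#' Derive stable-motif control sets for a target attractor
#'
#' @param net A `boolean_network`.
#' @param target Target attractor: an `attractor` object (steady state) or a
#'   named full 0/1 state vector.
#' @param diagram Optional precomputed [build_succession_diagram()].
#' @return List of `control_set` objects (`interventions`, `target`,
#'   `provenance` = the motif sequence the set was derived from), deduplicated
#'   and restricted to minimal sets. Empty, with a `diagnostic` attribute,
#'   when no motif sequence leads exclusively to the target.
#' @export
derive_control_sets <- function(net, target,
                                diagram = build_succession_diagram(net)) {
  tstate <- target_state_of(target, diagram$network_nodes)
  paths <- diagram_paths(diagram)
  exclusive <- Filter(function(p) {
    atts <- diagram$nodes[[p$sink]]$attractors
    length(atts) == 1L && atts[[1]]$kind == "steady_state" &&
      identical(unname(atts[[1]]$states[1, diagram$network_nodes]),
                unname(tstate))
  }, paths)
  if (length(exclusive) == 0L) {
    out <- list()
    attr(out, "diagnostic") <-
      "no motif sequence leads exclusively to the target attractor"
    return(out)
  }
  sets <- list()
  for (p in exclusive) {
    candidate <- integer(0)
    for (m in p$motifs) candidate <- c(candidate, m[setdiff(names(m),
                                                            names(candidate))])
    for (sub in minimal_certified_subsets(net, candidate, tstate)) {
      key <- paste(sprintf("%s=%d", names(sub), sub), collapse = ",")
      if (!key %in% names(sets))
        sets[[key]] <- structure(list(interventions = sub, target = tstate,
                                      provenance = p$motifs),
                                 class = "control_set")
    }
  }
  # keep only globally minimal sets
  ints <- lapply(sets, `[[`, "interventions")
  keep <- vapply(seq_along(ints), function(i)
    !any(vapply(seq_along(ints), function(j)
      j != i && length(ints[[j]]) < length(ints[[i]]) &&
        all(names(ints[[j]]) %in% names(ints[[i]])) &&
        all(ints[[i]][names(ints[[j]])] == ints[[j]]),
      logical(1))), logical(1))
  unname(sets[keep])
}

#' @export
print.control_set <- function(x, ...) {
  cat("control_set:",
      paste(sprintf("%s=%d", names(x$interventions), x$interventions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Dynamically verify a control set's effectiveness
#'
#' The interventions are clamped, the network is simulated under
#' random-order asynchronous updating until each trajectory's state has been
#' unchanged for `release_stable_rounds` consecutive rounds (the motif
#' sequence has locked in), the clamps are released, and the free dynamics
#' are run to a fixed point. Effectiveness is the fraction of initial states
#' whose final state equals the target; non-convergent trajectories count as
#' failures.
#'
#' @param net A `boolean_network` (unclamped; the control clamps are applied
#'   internally and transiently).
#' @param cs A `control_set`, or a named 0/1 vector of interventions.
#' @param target Target steady state (needed when `cs` is a plain vector).
#' @param init_states All-initial-states matrix, an integer (number of random
#'   initial states) or `"exhaustive"` (all `2^n`, n <= 16).
#' @param release_stable_rounds Consecutive unchanged rounds before release.
#' @param max_rounds Round budget for each of the two phases.
#' @param seed RNG seed.
#' @return Effectiveness in `[0, 1]`, with attribute `n` (trajectories).
#' @export
verify_control <- function(net, cs, target = NULL, init_states = "exhaustive",
                           release_stable_rounds = 3L, max_rounds = 100L,
                           seed = 1L) {
  if (inherits(cs, "control_set")) {
    if (is.null(target)) target <- cs$target
    cs <- cs$interventions
  }
  if (is.null(target)) stop("a target state is required")
  target <- target_state_of(target, net$nodes)
  n <- length(net$nodes)
  if (identical(init_states, "exhaustive")) {
    if (n > 16L) stop("exhaustive verification limited to 16 nodes")
    states <- all_states_matrix(net$nodes)
  } else if (is.matrix(init_states)) {
    states <- init_states[, net$nodes, drop = FALSE]
  } else {
    set.seed(seed)
    states <- matrix(sample(0:1, init_states * n, replace = TRUE),
                     ncol = n, dimnames = list(NULL, net$nodes))
  }
  set.seed(seed)
  m <- nrow(states)
  if (length(cs))
    states[, names(cs)] <- matrix(cs, nrow = m, ncol = length(cs), byrow = TRUE)
  released <- rep(FALSE, m)
  stable <- integer(m)

  # phase 1+2 interleaved: rows release individually once stable under clamp
  for (round in seq_len(2L * max_rounds)) {
    prev <- states
    states <- simulate_matrix(net, states, 1L, clamps = cs,
                              released = released)
    same <- rowSums(states != prev) == 0L
    stable <- ifelse(same, stable + 1L, 0L)
    newly <- !released & stable >= release_stable_rounds
    if (any(newly)) {
      released[newly] <- TRUE
      stable[newly] <- 0L
    }
    if (all(released) && all(next_state_matrix(net, states) == states)) break
  }
  hit <- rowSums(states != matrix(target, nrow = m, ncol = n,
                                  byrow = TRUE)) == 0L
  fixed <- rowSums(next_state_matrix(net, states) != states) == 0L
  eff <- mean(hit & fixed & released)
  attr(eff, "n") <- m
  eff
}

next_state_matrix <- function(net, states) {
  out <- states
  for (nd in net$nodes) out[, nd] <- rule_value_matrix(net$rules[[nd]], states)
  out
}
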