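#' Simulation configuration for stochastic Boolean dynamics
#'
#' @param n_runs Number of independent runs (paper-scale screens use 1000).
#' @param max_rounds Maximum update rounds per run; a run stops early once it
#'   reaches a fixed point.
#' @param scheme Update scheme. `"random_order"` (default): every free node
#'   is updated once per round in a fresh uniformly random permutation, each
#'   update seeing the latest state. `"general"`: a single uniformly chosen
#'   free node per round. `"synchronous"`: all free nodes simultaneously.
#'   `"ranked"`: like `"random_order"` but the permutation respects a
#'   user-supplied rank map (lower rank first, ties shuffled).
#' @param rank Named numeric vector of ranks, required for `scheme="ranked"`.
#' @param seed Integer RNG seed; every stochastic stage must be seeded.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_runs = 1000L, max_rounds = 100L,
                       scheme = c("random_order", "general", "synchronous",
                                  "ranked"),
                       rank = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_runs >= 1L, max_rounds >= 1L)
  if (scheme == "ranked" && is.null(rank))
    stop("scheme='ranked' requires a rank map")
  structure(list(n_runs = as.integer(n_runs),
                 max_rounds = as.integer(max_rounds),
                 scheme = scheme, rank = rank, seed = seed),
            class = "sim_config")
}

free_nodes <- function(net) setdiff(net$nodes, names(net$clamps))

#' Advance a network state by one update round
#'
#' Clamped nodes are never updated. Uses R's global RNG stream; seed the
#' stream (or use [run_simulations()]) for reproducibility.
#'
#' @param net A `boolean_network`.
#' @param state Named 0/1 vector over all nodes.
#' @param scheme,rank See [sim_config()].
#' @return Updated named 0/1 state vector.
#' @export
step_state <- function(net, state, scheme = "random_order", rank = NULL) {
  state <- as_network_state(net, state)
  free <- free_nodes(net)
  if (length(free) == 0L) return(state)
  if (scheme == "synchronous") {
    newv <- vapply(free, function(n) rule_value(net$rules[[n]], state),
                   integer(1))
    state[free] <- newv
    return(state)
  }
  ord <- switch(scheme,
    random_order = sample(free),
    general = sample(free, 1L),
    ranked = {
      if (is.null(rank) || !all(free %in% names(rank)))
        stop("ranked scheme requires a total rank map")
      free[order(rank[free], stats::runif(length(free)))]
    },
    stop(sprintf("unknown scheme '%s'", scheme)))
  for (n in ord) state[n] <- rule_value(net$rules[[n]], state)
  state
}

#' Run an ensemble of stochastic simulations and compute the transition
#' percentage readout
#'
#' Each run starts at `init` (clamped nodes forced to their clamp values),
#' iterates [step_state()] for up to `max_rounds` rounds and stops early at a
#' verified fixed point. Runs that do not reach a fixed point are flagged,
#' never dropped. The EMT% readout is the percentage of runs whose final
#' state has `readout` ON.
#'
#' @param net A `boolean_network` (perturbations already applied).
#' @param init Named 0/1 initial state.
#' @param config A [sim_config()].
#' @param readout Readout node name (default `"EMT"`).
#' @return `sim_outcome` with `final_states` (matrix, one row per run),
#'   `converged` (logical per run), `emt_percentage`, `readout`.
#' @export
run_simulations <- function(net, init, config = sim_config(),
                            readout = "EMT") {
  if (!readout %in% net$nodes)
    stop(sprintf("readout node '%s' not in network", readout))
  init <- as_network_state(net, init)
  cl <- net$clamps
  if (length(cl)) init[names(cl)] <- cl
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- length(net$nodes)
  finals <- matrix(NA_integer_, nrow = config$n_runs, ncol = n,
                   dimnames = list(NULL, net$nodes))
  converged <- logical(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    s <- init
    for (round in seq_len(config$max_rounds)) {
      s_new <- step_state(net, s, scheme = config$scheme, rank = config$rank)
      if (identical(unname(s_new), unname(s)) && is_fixed_point(net, s_new)) {
        converged[r] <- TRUE
        s <- s_new
        break
      }
      s <- s_new
    }
    if (!converged[r]) converged[r] <- is_fixed_point(net, s)
    finals[r, ] <- s
  }
  structure(list(final_states = finals, converged = converged,
                 emt_percentage = 100 * mean(finals[, readout] == 1L),
                 readout = readout, n_runs = config$n_runs),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("sim_outcome: %d runs, %s%% with %s ON, %d non-convergent\n",
              x$n_runs, format(x$emt_percentage), x$readout,
              sum(!x$converged)))
  invisible(x)
}

# Vectorized random-order asynchronous simulation of many trajectories at
# once. One permutation per round is shared across rows: each row still
# follows a valid random-order trajectory; rows are only used for mass
# verification sweeps, not for estimating inter-run variability. `clamps`
# overrides the rule value on rows where `released` is FALSE (transient
# control); clamps baked into `net` as constant rules apply to every row.
simulate_matrix <- function(net, states, rounds, clamps = integer(0),
                            released = rep(TRUE, nrow(states))) {
  for (round in seq_len(rounds)) {
    ord <- sample(net$nodes)
    for (n in ord) {
      newv <- rule_value_matrix(net$rules[[n]], states)
      if (n %in% names(clamps)) newv[!released] <- clamps[[n]]
      states[, n] <- newv
    }
  }
  states
}
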