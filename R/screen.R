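#' Combinatorial knockout / constitutive-activation screens
#'
#' The screen clamps combinations of candidate nodes OFF (knockout) or ON
#' (constitutive activation) in a signal-driven network, simulates each
#' combination from the epithelial-type initial state, and classifies
#' combinations whose transition readout is 0% across all runs as blockers.
#'
#' @name perturbation_screen
NULL

#' Number of combinations evaluated at a given order
#' @param pool_size Candidate pool size.
#' @param order Combination order.
#' @return `choose(pool_size, order)` as an exact integer count.
#' @export
screen_combination_count <- function(pool_size, order) {
  choose(pool_size, order)
}

#' Build the candidate pool for a screen order
#'
#' Order 1 uses every node except the excluded ones (by convention the input
#' signal, its receptor, the phenotype marker and the readout node). Order 2
#' removes the nodes whose individual knockout blocks the transition. Orders
#' 3 and 4 use the `"partner_removal"` rule: every node appearing in a fully
#' blocking pair is removed from the order-2 pool *except* the node common to
#' all blocking pairs (so the shared hub stays eligible); with
#' `pool_rule = "pairs_only"` only the exact blocking pairs are forbidden and
#' the pool is unchanged.
#'
#' @param net A `boolean_network`.
#' @param order Integer 1-4.
#' @param excluded_nodes Nodes never considered.
#' @param single_blockers Nodes whose single knockout blocks (required for
#'   order >= 2).
#' @param pair_blockers List of length-2 character vectors (required for
#'   order >= 3 under `"partner_removal"`).
#' @param pool_rule `"partner_removal"` (default) or `"pairs_only"`.
#' @return A `screen_plan` list with `order`, `pool`, `excluded`,
#'   `n_combinations`.
#' @export
build_pool <- function(net, order, excluded_nodes = character(0),
                       single_blockers = character(0),
                       pair_blockers = list(),
                       pool_rule = c("partner_removal", "pairs_only")) {
  pool_rule <- match.arg(pool_rule)
  if (!order %in% 1:4) stop("screen order must be between 1 and 4")
  miss <- setdiff(excluded_nodes, net$nodes)
  if (length(miss))
    stop(sprintf("excluded node '%s' not in network", miss[1]))
  pool <- setdiff(net$nodes, excluded_nodes)
  if (order >= 2L) pool <- setdiff(pool, single_blockers)
  if (order >= 3L && pool_rule == "partner_removal" && length(pair_blockers)) {
    members <- unique(unlist(pair_blockers))
    common <- Reduce(intersect, pair_blockers)
    pool <- setdiff(pool, setdiff(members, common))
  }
  structure(list(order = as.integer(order), pool = pool,
                 excluded = excluded_nodes, pool_rule = pool_rule,
                 n_combinations = screen_combination_count(length(pool), order)),
            class = "screen_plan")
}

#' @export
print.screen_plan <- function(x, ...) {
  cat(sprintf("screen_plan: order %d, pool %d nodes, %s combinations\n",
              x$order, length(x$pool), format(x$n_combinations, big.mark = ",")))
  invisible(x)
}

screen_one <- function(net, clamps, init, config, readout) {
  pnet <- apply_perturbation(net, clamps)
  out <- run_simulations(pnet, init, config, readout = readout)
  data.frame(
    combination = paste(names(clamps), collapse = "+"),
    clamps = paste(sprintf("%s=%d", names(clamps), clamps), collapse = ","),
    emt_pct = out$emt_percentage,
    blocker = out$emt_percentage == 0,
    all_converged = all(out$converged),
    stringsAsFactors = FALSE)
}

#' Run a knockout screen at a given order
#'
#' Every `order`-subset of the plan's pool is clamped OFF on top of `net`
#' (which should already carry the driving signal clamp, e.g. TGFb=ON), and
#' simulated with identical configuration from `init`.
#'
#' @param net Signal-driven `boolean_network`.
#' @param plan A [build_pool()] plan.
#' @param init Initial state (epithelial reference).
#' @param config A [sim_config()]; its `seed` is reused with a per-combination
#'   offset so the whole screen is reproducible.
#' @param readout Readout node.
#' @param partial_threshold Combinations with `0 < EMT% < partial_threshold`
#'   are flagged as partial suppressors (no printed threshold exists for
#'   "significantly decreased"; 50 is the configurable default).
#' @return `screen_result` with `results` (data.frame), `blockers`,
#'   `partial_suppressors`, `order`.
#' @export
run_screen <- function(net, plan, init, config = sim_config(),
                       readout = "EMT", partial_threshold = 50) {
  combos <- utils::combn(plan$pool, plan$order, simplify = FALSE)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  rows <- lapply(seq_along(combos), function(i) {
    cfg <- config
    cfg$seed <- base_seed + i
    screen_one(net, stats::setNames(rep(0L, plan$order), combos[[i]]),
               init, cfg, readout)
  })
  res <- do.call(rbind, rows)
  new_screen_result(res, plan$order, partial_threshold)
}

new_screen_result <- function(res, order, partial_threshold) {
  structure(list(
    results = res,
    blockers = res$combination[res$blocker],
    partial_suppressors =
      res$combination[!res$blocker & res$emt_pct < partial_threshold],
    order = order), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: order %d, %d combinations, %d blockers\n",
              x$order, nrow(x$results), length(x$blockers)))
  if (length(x$blockers))
    cat("  blockers:", paste(x$blockers, collapse = "; "), "\n")
  invisible(x)
}

#' Run the constitutive-activation / mixed screens
#'
#' `order = 1` clamps each pool node ON. `order = 2` evaluates every pair of
#' nodes with every knockout/activation sign assignment that contains at
#' least one activation, after removing single perturbations (either sign)
#' that block on their own.
#'
#' @inheritParams run_screen
#' @param order 1 or 2.
#' @param single_blocking_perturbations Character vector like `"miR200=1"` or
#'   `"SNAI1=0"`: single node-state perturbations that block individually and
#'   are therefore excluded from pairs.
#' @return `screen_result`.
#' @export
run_ca_screen <- function(net, plan, init, config = sim_config(),
                          readout = "EMT", order = 1L,
                          single_blocking_perturbations = character(0),
                          partial_threshold = 50) {
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  if (order == 1L) {
    rows <- lapply(seq_along(plan$pool), function(i) {
      cfg <- config; cfg$seed <- base_seed + i
      screen_one(net, stats::setNames(1L, plan$pool[i]), init, cfg, readout)
    })
    return(new_screen_result(do.call(rbind, rows), 1L, partial_threshold))
  }
  if (order != 2L) stop("mixed screens support orders 1 and 2")
  pairs <- utils::combn(plan$pool, 2L, simplify = FALSE)
  signs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L))
  rows <- list()
  i <- 0L
  for (pr in pairs) {
    for (sg in signs) {
      tag <- sprintf("%s=%d", pr, sg)
      if (any(tag %in% single_blocking_perturbations)) next
      i <- i + 1L
      cfg <- config; cfg$seed <- base_seed + i
      rows[[i]] <- screen_one(net, stats::setNames(sg, pr), init, cfg, readout)
    }
  }
  new_screen_result(do.call(rbind, rows), 2L, partial_threshold)
}
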