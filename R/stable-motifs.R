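#' Stable motifs, succession diagrams and attractors
#'
#' A stable motif is a self-sustaining generalized positive feedback loop: a
#' set of nodes forming a strongly connected component of the expanded
#' network together with one state per node, such that the states are a
#' partial fixed point of the update rules. Once the network enters the
#' motif's partial state it can never leave it, so motifs are points of no
#' return: fixing them and reducing the network, recursively, yields the
#' succession diagram whose sinks are the model's attractors.
#'
#' @name stable_motifs
NULL

# is the partial assignment `assign` (named 0/1 vector) a partial fixed point,
# i.e. does each assigned node's rule evaluate to its assigned value for every
# configuration of the unassigned inputs?
is_partial_fixed_point <- function(net, assign) {
  for (n in names(assign)) {
    r <- net$rules[[n]]
    tt <- r$tt
    inputs <- r$inputs
    fixed <- intersect(inputs, names(assign))
    for (f in fixed) {
      i <- match(f, inputs)
      tt <- tt_drop_input(tt, length(inputs), i, val = assign[[f]])
      inputs <- inputs[-i]
    }
    if (!all(tt == assign[[n]])) return(FALSE)
  }
  TRUE
}

support_strongly_connected <- function(net, nodes) {
  if (length(nodes) == 1L) {
    return(nodes %in% net$rules[[nodes]]$inputs)   # needs a functional self-loop
  }
  sub <- igraph::induced_subgraph(interaction_igraph(net), nodes)
  igraph::is_connected(sub, mode = "strong")
}

#' Find the stable motifs of a Boolean network
#'
#' A partial assignment is self-sustaining exactly when, for every assigned
#' node-state `n = s`, every prime implicant of `rule(n) == 1-s` contains a
#' literal contradicted by the assignment ("blocked"), so the rule can never
#' fire against the motif. Stable motifs are the inclusion-minimal nonempty
#' consistent assignments closed under this blocking condition (the minimal
#' trap spaces) whose support induces a strongly connected subgraph of the
#' interaction graph (a genuine feedback structure, not a percolation tail).
#'
#' The search seeds every node-state and grows the assignment along the
#' expanded network's implicant structure: an unblocked opposite implicant
#' branches over the literals that could block it. The search is complete:
#' every minimal closed assignment extends some seed through some branch.
#' Each reported motif is verified as a partial fixed point.
#'
#' @param net A `boolean_network`.
#' @param expanded Optional precomputed [build_expanded()] result (used for
#'   its prime-implicant structure when supplied).
#' @return List of named 0/1 vectors (one per motif), assignments ordered by
#'   the network's node order.
#' @export
find_stable_motifs <- function(net, expanded = NULL) {
  if (length(net$nodes) == 0L) return(list())
  # opposite-value prime implicants per (node, state), as literal assignments
  opp <- lapply(net$nodes, function(n) {
    r <- net$rules[[n]]
    lapply(c(`0` = 1L, `1` = 0L), function(v)
      lapply(prime_implicants(r$tt, length(r$inputs), value = v), function(p) {
        lits <- implicant_literals(p, r$inputs)
        stats::setNames(lits$value, lits$input)
      }))
  })
  names(opp) <- net$nodes

  closed_sets <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  key_of <- function(T) paste(sprintf("%s=%d", names(T), T), collapse = ",")

  first_unblocked <- function(T) {
    for (n in names(T)) {
      for (imp in opp[[n]][[as.character(T[[n]])]]) {
        if (length(imp) == 0L) return(list(node = n, imp = imp))  # unblockable
        hit <- names(imp)[!is.na(T[names(imp)]) & T[names(imp)] == 1L - imp]
        if (length(hit) == 0L) return(list(node = n, imp = imp))
      }
    }
    NULL
  }

  grow <- function(T) {
    T <- T[order(match(names(T), net$nodes))]
    k <- key_of(T)
    if (!is.null(seen[[k]])) return(invisible(NULL))
    seen[[k]] <- TRUE
    ub <- first_unblocked(T)
    if (is.null(ub)) {
      closed_sets[[k]] <- T
      return(invisible(NULL))
    }
    if (length(ub$imp) == 0L) return(invisible(NULL))  # constant opposite: dead
    for (u in names(ub$imp)) {
      want <- 1L - ub$imp[[u]]
      if (!is.na(T[u])) next                           # conflicting, branch dead
      T2 <- c(T, stats::setNames(want, u))
      grow(T2)
    }
  }

  for (n in net$nodes) for (s in 0:1) grow(stats::setNames(as.integer(s), n))

  cand <- as.list(closed_sets)
  if (length(cand) == 0L) return(list())
  # inclusion-minimal closed assignments only
  keep <- vapply(seq_along(cand), function(i)
    !any(vapply(seq_along(cand), function(j)
      j != i && length(cand[[j]]) < length(cand[[i]]) &&
        all(names(cand[[j]]) %in% names(cand[[i]])) &&
        all(cand[[i]][names(cand[[j]])] == cand[[j]]),
      logical(1))), logical(1))
  cand <- cand[keep]
  motifs <- Filter(function(m)
    support_strongly_connected(net, names(m)) &&
      is_partial_fixed_point(net, m), cand)
  unname(motifs)
}

# ---- network reduction ------------------------------------------------------

substitute_constant <- function(rule, node, value) {
  i <- match(node, rule$inputs)
  if (is.na(i)) return(rule)
  rule$tt <- tt_drop_input(rule$tt, length(rule$inputs), i, val = value)
  rule$inputs <- rule$inputs[-i]
  prune_rule(rule)
}

# fix `assign`, substitute, then iteratively fix any node whose rule becomes
# constant; returns list(net = reduced network over remaining nodes,
# fixed = all node states fixed so far)
propagate_constants <- function(net, assign = integer(0)) {
  fixed <- stats::setNames(as.integer(assign), names(assign))
  repeat {
    changed <- FALSE
    for (n in setdiff(net$nodes, names(fixed))) {
      r <- net$rules[[n]]
      for (f in intersect(r$inputs, names(fixed)))
        r <- substitute_constant(r, f, fixed[[f]])
      net$rules[[n]] <- r
      if (length(r$inputs) == 0L) {
        fixed[n] <- r$tt[1]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- setdiff(net$nodes, names(fixed))
  red <- new_boolean_network(keep, net$rules[keep],
                             clamps = net$clamps[intersect(names(net$clamps), keep)])
  list(net = red, fixed = fixed[order(match(names(fixed), net$nodes))])
}

#' Reduce a network by fixing a stable motif
#'
#' The motif's node states are substituted as constants into the remaining
#' rules; any rule that becomes constant fixes its node in turn, and the
#' propagation repeats to closure. The reduced network carries the full fixed
#' assignment in `attr(, "fixed")`.
#'
#' @param net A `boolean_network`.
#' @param motif Named 0/1 vector, a stable motif (partial fixed point) of `net`.
#' @return Reduced `boolean_network` over the remaining free nodes.
#' @export
reduce_network <- function(net, motif) {
  if (!is_partial_fixed_point(net, motif))
    stop("assignment is not a partial fixed point; cannot reduce")
  pr <- propagate_constants(net, motif)
  structure(pr$net, fixed = pr$fixed)
}

# ---- succession diagram -----------------------------------------------------

fixed_key <- function(fixed) {
  if (length(fixed) == 0L) return("<root>")
  paste(sprintf("%s=%d", names(fixed), fixed), collapse = ",")
}

#' Build the stable-motif succession diagram
#'
#' Starting from the (constant-propagated) network, stable motifs are found,
#' fixed and reduced, recursively; reduced networks reached by different
#' motif orderings are shared (memoized by their fixed assignment). Diagram
#' sinks carry attractors: when all nodes are fixed the sink is a steady
#' state; when free nodes remain but no motif exists, the leftover network's
#' attractors are enumerated exhaustively (up to `max_exact` free nodes) or,
#' beyond that, approximated by stochastic simulation and flagged.
#'
#' @param net A `boolean_network`.
#' @param max_exact Largest leftover network (free nodes) enumerated exactly.
#' @param sim_runs Trajectories used per leftover network in approximate mode.
#' @return Object of class `succession_diagram`: list of diagram nodes, each
#'   with `fixed`, `motifs`, `children` (keys per motif) and, for sinks,
#'   `attractors` (list of `attractor` objects).
#' @export
build_succession_diagram <- function(net, max_exact = 16L, sim_runs = 200L) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  orig_nodes <- net$nodes
  approx <- FALSE

  complete_state <- function(fixed, leftover_state = integer(0)) {
    s <- c(fixed, leftover_state)
    stats::setNames(as.integer(s[orig_nodes]), orig_nodes)
  }

  explore <- function(red, fixed) {
    key <- fixed_key(fixed)
    if (!is.null(env$nodes[[key]])) return(key)
    entry <- list(fixed = fixed, motifs = list(), children = character(0),
                  attractors = NULL)
    env$nodes[[key]] <- entry                       # reserve before recursing
    motifs <- find_stable_motifs(red)
    if (length(motifs) == 0L) {
      if (length(red$nodes) == 0L) {
        att <- list(new_attractor("steady_state",
                                  matrix(complete_state(fixed), nrow = 1,
                                         dimnames = list(NULL, orig_nodes))))
      } else if (length(red$nodes) <= max_exact) {
        sub_atts <- brute_force_attractors(red)
        att <- lapply(sub_atts, function(a) {
          sts <- t(apply(a$states, 1, function(row)
            complete_state(fixed, stats::setNames(row, colnames(a$states)))))
          colnames(sts) <- orig_nodes
          new_attractor(a$kind, sts)
        })
      } else {
        approx <<- TRUE
        att <- approximate_attractors(red, fixed, complete_state, sim_runs)
      }
      entry$attractors <- att
      env$nodes[[key]] <- entry
      return(key)
    }
    entry$motifs <- motifs
    kids <- character(length(motifs))
    for (i in seq_along(motifs)) {
      pr <- propagate_constants(red, motifs[[i]])
      kids[i] <- explore(pr$net, c(fixed, pr$fixed))
    }
    entry$children <- kids
    env$nodes[[key]] <- entry
    key
  }

  pr0 <- propagate_constants(net)
  root <- explore(pr0$net, pr0$fixed)
  structure(list(nodes = env$nodes, root = root, network_nodes = orig_nodes,
                 approximate = approx),
            class = "succession_diagram")
}

approximate_attractors <- function(red, fixed, complete_state, sim_runs) {
  init <- matrix(sample(0:1, sim_runs * length(red$nodes), replace = TRUE),
                 nrow = sim_runs, dimnames = list(NULL, red$nodes))
  fin <- simulate_matrix(red, init, rounds = 200L)
  fp <- vapply(seq_len(nrow(fin)), function(i)
    is_fixed_point(red, fin[i, ]), logical(1))
  sts <- unique(fin[fp, , drop = FALSE])
  atts <- lapply(seq_len(nrow(sts)), function(i) {
    full <- complete_state(fixed, stats::setNames(sts[i, ], red$nodes))
    new_attractor("steady_state",
                  matrix(full, nrow = 1,
                         dimnames = list(NULL, names(full))),
                  approximate = TRUE)
  })
  if (any(!fp))
    atts <- c(atts, list(new_attractor(
      "complex", unique(fin[!fp, , drop = FALSE]), approximate = TRUE)))
  atts
}

#' @export
print.succession_diagram <- function(x, ...) {
  sinks <- Filter(function(e) !is.null(e$attractors), x$nodes)
  cat(sprintf("succession_diagram: %d nodes, %d sinks%s\n",
              length(x$nodes), length(sinks),
              if (x$approximate) " (approximate)" else ""))
  invisible(x)
}

diagram_sinks <- function(diagram) {
  Filter(function(e) !is.null(e$attractors), diagram$nodes)
}

# all root-to-sink motif sequences; returns list of
# list(motifs = list of motif assignments, sink = key)
diagram_paths <- function(diagram) {
  out <- list()
  walk <- function(key, motifs_so_far) {
    e <- diagram$nodes[[key]]
    if (!is.null(e$attractors)) {
      out[[length(out) + 1L]] <<- list(motifs = motifs_so_far, sink = key)
      return(invisible(NULL))
    }
    for (i in seq_along(e$motifs))
      walk(e$children[i], c(motifs_so_far, list(e$motifs[[i]])))
  }
  walk(diagram$root, list())
  out
}

# ---- attractors -------------------------------------------------------------

new_attractor <- function(kind, states, approximate = FALSE) {
  structure(list(kind = kind, states = states, approximate = approximate),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("attractor (%s%s): %d state(s)\n", x$kind,
              if (x$approximate) ", approximate" else "", nrow(x$states)))
  invisible(x)
}

attractor_key <- function(a) {
  rows <- sort(apply(a$states, 1, paste, collapse = ""))
  paste(a$kind, paste(rows, collapse = "|"))
}

#' Enumerate the attractors of a Boolean network via stable motifs
#'
#' Builds the succession diagram and collects the deduplicated attractors of
#' its sinks. Steady states are verified against the update rules; the result
#' is flagged approximate when any leftover network exceeded the exact
#' enumeration budget.
#'
#' @inheritParams build_succession_diagram
#' @param diagram Optional precomputed succession diagram.
#' @return List of `attractor` objects, each with `kind`
#'   (`"steady_state"`/`"complex"`), a `states` matrix (rows are states) and
#'   an `approximate` flag.
#' @export
find_attractors <- function(net, max_exact = 16L, sim_runs = 200L,
                            diagram = NULL) {
  if (is.null(diagram))
    diagram <- build_succession_diagram(net, max_exact = max_exact,
                                        sim_runs = sim_runs)
  atts <- unname(unlist(lapply(diagram_sinks(diagram), `[[`, "attractors"),
                        recursive = FALSE))
  atts <- atts[!duplicated(vapply(atts, attractor_key, character(1)))]
  for (a in atts)
    if (a$kind == "steady_state" &&
        !is_fixed_point(net, stats::setNames(a$states[1, ], colnames(a$states))))
      stop("internal error: sink state is not a fixed point")
  atts
}
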