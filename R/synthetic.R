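#' Synthetic Boolean networks with known ground truth
#'
#' The generator emits small random networks containing *planted* stable
#' motifs: a sign-consistent feedback cycle over a chosen node set, wired so
#' that the requested partial state (and its complement) is self-sustaining.
#' Remaining nodes receive random rules over randomly drawn inputs. Every
#' emitted network is small enough for the brute-force oracles, so the whole
#' pipeline (motifs, attractors, control, projection) can be tested against
#' exhaustive enumeration without any external model file.
#'
#' @name synthetic_networks
NULL

#' Specification for a synthetic toy network
#'
#' @param n_nodes Total node count (at most 16 so oracles stay exhaustive).
#' @param planted_motif Named 0/1 vector: the node states to plant as a
#'   feedback cycle (names may be any identifiers; missing nodes are created).
#' @param in_degree In-degree for the non-planted random nodes.
#' @param rng_seed Integer seed; the same spec and seed give the same network.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_nodes, planted_motif = NULL, in_degree = 2L,
                     rng_seed = 1L) {
  stopifnot(n_nodes >= 1L, n_nodes <= 16L)
  if (!is.null(planted_motif) && length(planted_motif) > n_nodes)
    stop("planted motif larger than the network")
  structure(list(n_nodes = as.integer(n_nodes), planted_motif = planted_motif,
                 in_degree = as.integer(in_degree),
                 rng_seed = as.integer(rng_seed)),
            class = "toy_spec")
}

#' Generate a toy network with planted motifs and its ground truth
#'
#' The planted node set is wired as a directed cycle in which node `i`'s rule
#' is the literal of its cycle predecessor that matches the planted states
#' (`pred` if the two states agree, `!pred` otherwise), making the planted
#' assignment and its complement stable motifs by construction. Other nodes
#' get a random rule (random truth table) over inputs drawn uniformly from
#' the whole node set; inputs without functional influence are pruned.
#'
#' @param spec A [toy_spec()].
#' @return List with `net`, `ground_truth` (list with `motifs` from
#'   [brute_force_motifs()] and `attractors` from [brute_force_attractors()]),
#'   and `planted` (the planted motif and its complement).
#' @export
generate_toy <- function(spec) {
  set.seed(spec$rng_seed)
  pm <- spec$planted_motif
  pnodes <- names(pm)
  extra <- max(0L, spec$n_nodes - length(pnodes))
  others <- setdiff(sprintf("N%d", seq_len(spec$n_nodes)), pnodes)[seq_len(extra)]
  nodes <- c(pnodes, others)

  lines <- character(0)
  if (length(pnodes) > 0L) {
    if (length(pnodes) == 1L) {
      lines <- c(lines, paste0(pnodes, ", ", pnodes))
    } else {
      pred <- c(pnodes[length(pnodes)], pnodes[-length(pnodes)])
      for (i in seq_along(pnodes)) {
        lit <- if (pm[[i]] == pm[[match(pred[i], pnodes)]]) pred[i]
               else paste0("!", pred[i])
        lines <- c(lines, paste0(pnodes[i], ", ", lit))
      }
    }
  }
  for (n in others) {
    k <- min(spec$in_degree, length(nodes))
    ins <- sample(nodes, k)
    tt <- sample(0:1, 2^k, replace = TRUE)
    terms <- which(tt == 1L) - 1L
    if (length(terms) == 0L) {
      lines <- c(lines, paste0(n, ", 0"))
    } else if (length(terms) == 2^k) {
      lines <- c(lines, paste0(n, ", 1"))
    } else {
      dnf <- vapply(terms, function(m) {
        bits <- bitwAnd(m, 2^(seq_len(k) - 1)) != 0
        paste0("(", paste(ifelse(bits, ins, paste0("!", ins)),
                          collapse = " & "), ")")
      }, character(1))
      lines <- c(lines, paste0(n, ", ", paste(dnf, collapse = " | ")))
    }
  }
  net <- parse_boolean_network(lines)

  planted <- list()
  if (length(pm)) {
    planted <- list(pm, stats::setNames(1L - pm, names(pm)))
    for (p in planted)
      if (!is_partial_fixed_point(net, p))
        stop("internal error: planted assignment is not a partial fixed point")
  }
  gt <- list(
    motifs = if (spec$n_nodes <= 10L) brute_force_motifs(net) else NULL,
    attractors = brute_force_attractors(net))
  list(net = net, ground_truth = gt, planted = planted)
}

# ---- brute-force oracles ----------------------------------------------------

all_states_matrix <- function(nodes) {
  n <- length(nodes)
  m <- sapply(seq_len(n), function(i)
    rep(rep(0:1, each = 2^(i - 1)), length.out = 2^n))
  m <- matrix(as.integer(m), nrow = 2^n, dimnames = list(NULL, nodes))
  m
}

#' Exhaustive attractor enumeration (oracle)
#'
#' Steady states come from a full `2^n` fixed-point scan. Complex attractors
#' are the non-singleton terminal strongly connected components of the
#' general-asynchronous state-transition graph (one node updated per step);
#' round-based asynchronous schemes share its fixed points.
#'
#' @param net A `boolean_network` with at most 16 nodes.
#' @return List of `attractor` objects.
#' @export
brute_force_attractors <- function(net) {
  n <- length(net$nodes)
  if (n > 16L) stop("brute-force attractor scan limited to 16 nodes")
  if (n == 0L) return(list())
  states <- all_states_matrix(net$nodes)
  nxt <- sapply(net$nodes, function(nd) rule_value_matrix(net$rules[[nd]], states))
  nxt <- matrix(as.integer(nxt), nrow = nrow(states),
                dimnames = list(NULL, net$nodes))
  fixed <- rowSums(nxt != states) == 0L
  atts <- lapply(which(fixed), function(i)
    new_attractor("steady_state", states[i, , drop = FALSE]))

  # general-asynchronous STG; only non-fixed behaviour can add complex attractors
  weights <- 2^(seq_len(n) - 1)
  id <- seq_len(2^n)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(n)) {
    diff <- nxt[, j] != states[, j]
    if (any(diff)) {
      tgt <- id[diff] + (nxt[diff, j] - states[diff, j]) * weights[j]
      from <- c(from, id[diff]); to <- c(to, tgt)
    }
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    g <- igraph::add_vertices(g, max(0, 2^n - igraph::vcount(g)))
    comp <- igraph::components(g, mode = "strong")
    cond_edges <- unique(cbind(comp$membership[from], comp$membership[to]))
    terminal <- setdiff(seq_len(comp$no),
                        cond_edges[cond_edges[, 1] != cond_edges[, 2], 1])
    for (ci in terminal) {
      members <- which(comp$membership == ci)
      if (length(members) > 1L)
        atts <- c(atts, list(new_attractor(
          "complex", states[members, , drop = FALSE])))
    }
  }
  atts
}

#' Exhaustive stable-motif enumeration (oracle)
#'
#' Enumerates every partial assignment and keeps the inclusion-minimal
#' partial fixed points whose support induces a strongly connected subgraph
#' of the interaction graph: the smallest self-sustaining feedback
#' assignments (minimal trap spaces with feedback support), matching the
#' motif definition used by [find_stable_motifs()] by an independent route.
#'
#' @param net A `boolean_network` with at most 10 nodes.
#' @return List of named 0/1 vectors.
#' @export
brute_force_motifs <- function(net) {
  n <- length(net$nodes)
  if (n > 10L) stop("brute-force motif scan limited to 10 nodes")
  if (n == 0L) return(list())

  valid <- list()
  for (sz in seq_len(n)) {
    for (sub in utils::combn(seq_len(n), sz, simplify = FALSE)) {
      nodes <- net$nodes[sub]
      vals <- all_states_matrix(nodes)
      for (i in seq_len(nrow(vals))) {
        assign <- stats::setNames(vals[i, ], nodes)
        if (is_partial_fixed_point(net, assign))
          valid[[length(valid) + 1L]] <- assign
      }
    }
  }
  if (length(valid) == 0L) return(valid)
  contained <- function(a, b) {  # a strictly contained in b
    length(a) < length(b) && all(names(a) %in% names(b)) &&
      all(b[names(a)] == a)
  }
  keep <- vapply(seq_along(valid), function(i)
    !any(vapply(seq_along(valid), function(j)
      i != j && contained(valid[[j]], valid[[i]]), logical(1))),
    logical(1))
  Filter(function(m) support_strongly_connected(net, names(m)), valid[keep])
}
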