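#' Boolean network objects
#'
#' A `boolean_network` stores an ordered node list and, per node, an update
#' rule represented as a truth table over that node's *functional* inputs
#' (inputs on which the rule value actually depends). Rules are entered in a
#' bnet-style text dialect, one `target, expression` line per node, with
#' operators `&`, `|`, `!` (word aliases `AND`, `OR`, `NOT`), parentheses and
#' the constants `0`/`1`.
#'
#' The truth-table representation makes rule evaluation, restriction under
#' clamps, prime-implicant computation and functional-dependence analysis
#' exact and uniform. Input bit `i` of a rule is the state of `inputs[i]`;
#' the table entry for input states `v` is `tt[1 + sum(v * 2^(i-1))]`.
#'
#' @name boolean_network
NULL

new_rule <- function(inputs, tt) {
  stopifnot(length(tt) == 2^length(inputs))
  list(inputs = inputs, tt = as.integer(tt))
}

new_boolean_network <- function(nodes, rules, clamps = integer(0)) {
  structure(list(nodes = nodes, rules = rules, clamps = clamps),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d nodes, %d interaction edges\n",
              length(x$nodes), nrow(interaction_graph(x))))
  if (length(x$clamps))
    cat("  clamped:", paste(sprintf("%s=%d", names(x$clamps), x$clamps),
                            collapse = ", "), "\n")
  invisible(x)
}

# ---- parsing ----------------------------------------------------------------

tokenize_rule_text <- function(expr_text) {
  # word aliases -> symbolic operators; case-insensitive, word-bounded
  expr_text <- gsub("\\bAND\\b", "&", expr_text, ignore.case = TRUE)
  expr_text <- gsub("\\bOR\\b", "|", expr_text, ignore.case = TRUE)
  expr_text <- gsub("\\bNOT\\b", "!", expr_text, ignore.case = TRUE)
  expr_text
}

check_rule_ast <- function(e, line) {
  if (is.symbol(e) || (is.numeric(e) && e %in% c(0, 1))) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op %in% c("&", "|", "&&", "||")) {
      check_rule_ast(e[[2]], line); check_rule_ast(e[[3]], line)
      return(invisible(TRUE))
    }
    if (op %in% c("!", "(")) {
      check_rule_ast(e[[2]], line)
      return(invisible(TRUE))
    }
  }
  stop(sprintf("line %d: unsupported construct '%s' in rule expression",
               line, deparse1(e)), call. = FALSE)
}

rule_truth_table <- function(expr, inputs, line, max_inputs = 16L) {
  k <- length(inputs)
  if (k > max_inputs)
    stop(sprintf("line %d: rule has %d inputs; at most %d supported",
                 line, k, max_inputs), call. = FALSE)
  if (k == 0L) {
    v <- eval(expr, envir = baseenv())
    return(as.integer(as.logical(v)))
  }
  grid <- lapply(seq_len(k), function(i)
    rep(rep(0:1, each = 2^(i - 1)), length.out = 2^k))
  names(grid) <- inputs
  v <- eval(expr, envir = grid, enclos = baseenv())
  as.integer(rep_len(as.logical(v), 2^k))
}

# drop an input bit; val = NULL removes a non-functional input,
# val = 0/1 restricts (substitutes a constant)
tt_drop_input <- function(tt, k, i, val = NULL) {
  if (is.null(val)) val <- 0L
  j <- 0:(2^(k - 1) - 1)
  low <- j %% 2^(i - 1)
  high <- j %/% 2^(i - 1)
  tt[1 + low + val * 2^(i - 1) + high * 2^i]
}

functional_inputs <- function(tt, k) {
  if (k == 0L) return(logical(0))
  idx <- 0:(2^k - 1)
  vapply(seq_len(k), function(i) {
    lo <- idx[bitwAnd(idx, 2^(i - 1)) == 0]
    any(tt[lo + 1] != tt[lo + 2^(i - 1) + 1])
  }, logical(1))
}

# canonicalize input order (declaration order of the network) so that
# semantically identical rules compare identical
reorder_rule_inputs <- function(rule, node_order) {
  k <- length(rule$inputs)
  if (k <= 1L) return(rule)
  ord <- order(match(rule$inputs, node_order))
  if (all(ord == seq_len(k))) return(rule)
  idx <- 0:(2^k - 1)
  old_idx <- integer(2^k)
  for (i in seq_len(k))
    old_idx <- old_idx +
      as.integer(bitwAnd(idx, 2^(i - 1)) != 0) * 2^(ord[i] - 1)
  rule$tt <- rule$tt[old_idx + 1]
  rule$inputs <- rule$inputs[ord]
  rule
}

prune_rule <- function(rule) {
  repeat {
    k <- length(rule$inputs)
    dep <- functional_inputs(rule$tt, k)
    if (all(dep)) return(rule)
    i <- which(!dep)[1]
    rule$tt <- tt_drop_input(rule$tt, k, i)
    rule$inputs <- rule$inputs[-i]
  }
}

#' Parse a Boolean network from rule text
#'
#' One `target, expression` line per node. Lines starting with `#` are
#' comments; an optional `targets, factors` header line is ignored. Every
#' identifier appearing in an expression must be a declared target. Inputs
#' without functional influence on a rule (e.g. `B` in `B & !B | C`) are
#' pruned, so the interaction graph reflects functional dependence.
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @return A `boolean_network`.
#' @export
parse_boolean_network <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- data.frame(line = seq_along(lines), text = lines)
  raw$text <- sub("#.*$", "", raw$text)
  raw <- raw[trimws(raw$text) != "", , drop = FALSE]
  raw <- raw[!grepl("^\\s*targets\\s*,\\s*factors\\s*$", raw$text,
                    ignore.case = TRUE), , drop = FALSE]
  if (nrow(raw) == 0L) stop("no rules found", call. = FALSE)

  targets <- character(0)
  exprs <- list()
  lineno <- integer(0)
  for (r in seq_len(nrow(raw))) {
    ln <- raw$line[r]
    parts <- regmatches(raw$text[r], regexpr(",", raw$text[r]), invert = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: expected 'target, expression'", ln), call. = FALSE)
    tgt <- trimws(parts[1])
    if (!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", tgt))
      stop(sprintf("line %d: invalid node identifier '%s'", ln, tgt),
           call. = FALSE)
    if (tgt %in% targets)
      stop(sprintf("line %d: duplicate target '%s'", ln, tgt), call. = FALSE)
    etxt <- tokenize_rule_text(trimws(parts[2]))
    e <- tryCatch(str2lang(etxt), error = function(err)
      stop(sprintf("line %d: cannot parse expression '%s'", ln, parts[2]),
           call. = FALSE))
    check_rule_ast(e, ln)
    targets <- c(targets, tgt)
    exprs[[tgt]] <- e
    lineno <- c(lineno, ln)
  }

  rules <- vector("list", length(targets))
  names(rules) <- targets
  for (j in seq_along(targets)) {
    e <- exprs[[targets[j]]]
    vars <- all.vars(e)
    bad <- setdiff(vars, targets)
    if (length(bad))
      stop(sprintf("line %d: undeclared identifier '%s' in rule for '%s'",
                   lineno[j], bad[1], targets[j]), call. = FALSE)
    tt <- rule_truth_table(e, vars, lineno[j])
    rules[[j]] <- reorder_rule_inputs(prune_rule(new_rule(vars, tt)), targets)
  }
  new_boolean_network(targets, rules)
}

#' Read a Boolean network rule file
#' @param path Path to a bnet-style rule file.
#' @return A `boolean_network`.
#' @export
read_boolean_network <- function(path) {
  parse_boolean_network(readLines(path, warn = FALSE))
}

# ---- serialization ----------------------------------------------------------

implicant_to_text <- function(lits) {
  if (nrow(lits) == 0L) return("1")
  paste(ifelse(lits$value == 1L, lits$input, paste0("!", lits$input)),
        collapse = " & ")
}

rule_to_text <- function(rule) {
  k <- length(rule$inputs)
  if (k == 0L) return(as.character(rule$tt[1]))
  pis <- prime_implicants(rule$tt, k, value = 1L)
  if (length(pis) == 0L) return("0")
  terms <- vapply(pis, function(p) {
    pos <- which(bitwAnd(p["mask"], 2^(seq_len(k) - 1)) != 0)
    lits <- data.frame(
      input = rule$inputs[pos],
      value = as.integer(bitwAnd(p["bits"], 2^(pos - 1)) != 0))
    txt <- implicant_to_text(lits)
    if (nrow(lits) > 1L) paste0("(", txt, ")") else txt
  }, character(1))
  paste(sort(terms), collapse = " | ")
}

#' Serialize a Boolean network to rule text
#'
#' Rules are written in canonical disjunctive normal form (the disjunction of
#' all prime implicants), so `parse(serialize(parse(text)))` reproduces node
#' order and rule truth tables exactly.
#'
#' @param net A `boolean_network`.
#' @return Character vector of lines, first line `targets, factors`.
#' @export
serialize_boolean_network <- function(net) {
  c("targets, factors",
    vapply(net$nodes, function(n)
      paste0(n, ", ", rule_to_text(net$rules[[n]])), character(1)))
}

#' Write a Boolean network rule file
#' @param net A `boolean_network`.
#' @param path Output path.
#' @export
write_boolean_network <- function(net, path) {
  writeLines(serialize_boolean_network(net), path)
  invisible(path)
}

# ---- evaluation -------------------------------------------------------------

rule_value <- function(rule, state) {
  k <- length(rule$inputs)
  if (k == 0L) return(rule$tt[1])
  rule$tt[1L + sum(state[rule$inputs] * 2^(seq_len(k) - 1))]
}

# vectorized over a 0/1 state matrix (rows = states, columns = all net nodes)
rule_value_matrix <- function(rule, states) {
  k <- length(rule$inputs)
  if (k == 0L) return(rep.int(rule$tt[1], nrow(states)))
  idx <- as.vector(states[, rule$inputs, drop = FALSE] %*% 2^(seq_len(k) - 1))
  rule$tt[1L + idx]
}

#' Evaluate one node's update rule at a network state
#'
#' @param net A `boolean_network`.
#' @param node Node identifier.
#' @param state Named 0/1 vector assigning every node.
#' @return 0 or 1.
#' @export
evaluate_rule <- function(net, node, state) {
  if (!node %in% net$nodes) stop(sprintf("unknown node '%s'", node))
  state <- as_network_state(net, state)
  rule_value(net$rules[[node]], state)
}

as_network_state <- function(net, state) {
  if (is.null(names(state)) && length(state) == length(net$nodes))
    names(state) <- net$nodes
  miss <- setdiff(net$nodes, names(state))
  if (length(miss))
    stop(sprintf("state is missing nodes: %s", paste(miss, collapse = ", ")))
  s <- as.integer(state[net$nodes])
  if (anyNA(s) || !all(s %in% 0:1)) stop("state entries must be 0/1")
  names(s) <- net$nodes
  s
}

#' Test whether a state is a fixed point of all update rules
#' @param net A `boolean_network`.
#' @param state Named 0/1 vector over all nodes.
#' @return Logical scalar.
#' @export
is_fixed_point <- function(net, state) {
  state <- as_network_state(net, state)
  all(vapply(net$nodes, function(n)
    rule_value(net$rules[[n]], state) == state[[n]], logical(1)))
}

# ---- perturbations ----------------------------------------------------------

#' Clamp nodes to fixed states (knockout / constitutive activation)
#'
#' Clamped nodes have their update rules replaced by constants (the rule is
#' ignored for the duration of the perturbation) and are never updated by the
#' simulator; all other rules are untouched.
#'
#' @param net A `boolean_network`.
#' @param clamps Named 0/1 vector, e.g. `c(SMAD = 0, TGFb = 1)`; 0 is a
#'   knockout, 1 a constitutive activation.
#' @return A perturbed `boolean_network`.
#' @export
apply_perturbation <- function(net, clamps) {
  if (length(clamps) == 0L) return(net)
  clamps <- as.integer(clamps) |> stats::setNames(names(clamps))
  if (is.null(names(clamps)) || any(names(clamps) == ""))
    stop("clamps must be a named vector")
  if (anyDuplicated(names(clamps)))
    stop("clamped nodes must be distinct")
  bad <- setdiff(names(clamps), net$nodes)
  if (length(bad))
    stop(sprintf("cannot clamp unknown node '%s'", bad[1]))
  if (!all(clamps %in% 0:1)) stop("clamp values must be 0/1")
  for (n in names(clamps))
    net$rules[[n]] <- new_rule(character(0), clamps[[n]])
  net$clamps <- c(net$clamps[setdiff(names(net$clamps), names(clamps))], clamps)
  net
}

#' Nodes whose rule is themselves or a constant
#' @param net A `boolean_network`.
#' @return Character vector of source node names.
#' @export
source_nodes <- function(net) {
  net$nodes[vapply(net$nodes, function(n) {
    r <- net$rules[[n]]
    length(r$inputs) == 0L || identical(r$inputs, n)
  }, logical(1))]
}

# ---- interaction graph ------------------------------------------------------

#' Signed interaction graph under functional dependence
#'
#' An edge `u -> v` exists iff flipping `u` changes `v`'s rule value in some
#' context. The sign is `+1`/`-1` when the rule is monotone
#' increasing/decreasing in that input and `NA` otherwise.
#'
#' @param net A `boolean_network`.
#' @return `data.frame` with columns `from`, `to`, `sign`.
#' @export
interaction_graph <- function(net) {
  rows <- lapply(net$nodes, function(v) {
    r <- net$rules[[v]]
    k <- length(r$inputs)
    if (k == 0L) return(NULL)
    idx <- 0:(2^k - 1)
    sg <- vapply(seq_len(k), function(i) {
      lo <- idx[bitwAnd(idx, 2^(i - 1)) == 0]
      d <- r$tt[lo + 2^(i - 1) + 1] - r$tt[lo + 1]
      if (all(d >= 0)) 1 else if (all(d <= 0)) -1 else NA_real_
    }, numeric(1))
    data.frame(from = r$inputs, to = v, sign = sg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(from = character(0), to = character(0),
                                      sign = numeric(0))
  rownames(out) <- NULL
  out
}

interaction_igraph <- function(net) {
  ig <- interaction_graph(net)
  igraph::graph_from_data_frame(ig[, c("from", "to")], directed = TRUE,
                                vertices = net$nodes)
}

# ---- reference states -------------------------------------------------------

#' Read named network states from a two-column table
#'
#' The file holds one `node` column plus one 0/1 column per state (e.g.
#' epithelial and mesenchymal reference steady states).
#'
#' @param path Path to a TSV with header `node` plus one column per state.
#' @return Named list of named 0/1 state vectors.
#' @export
read_network_states <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lapply(df[-1], function(col) stats::setNames(as.integer(col), df[[1]]))
}

#' Write named network states to a two-column table
#' @param states Named list of named 0/1 vectors (identical node sets).
#' @param path Output path.
#' @export
write_network_states <- function(states, path) {
  nodes <- names(states[[1]])
  df <- data.frame(node = nodes, check.names = FALSE)
  for (nm in names(states)) df[[nm]] <- as.integer(states[[nm]][nodes])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
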