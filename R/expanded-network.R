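#' Build the expanded network of a Boolean model
#'
#' The expanded network is the auxiliary graph used to locate stable motifs.
#' Each node `n` contributes two *virtual* nodes, `n=1` and `n=0`. For every
#' prime implicant of `rule(n) == s`, edges are added into the virtual node
#' `n=s`: directly from the literal's virtual node when the implicant has a
#' single literal, or through a *composite* node (one per distinct literal
#' set) that receives an edge from each literal's virtual node. Composite
#' nodes encode conjunctions; a constant rule contributes no incoming edges.
#'
#' @param net A `boolean_network`.
#' @return List with `graph` (igraph), `virtual` (character vector of virtual
#'   node names), `composite` (named list mapping composite node name to its
#'   input virtual nodes).
#' @export
build_expanded <- function(net) {
  if (length(net$nodes) == 0L)
    return(list(graph = igraph::make_empty_graph(directed = TRUE),
                virtual = character(0), composite = list()))
  vname <- function(node, s) paste0(node, "=", s)
  virtual <- as.vector(t(outer(net$nodes, 0:1, vname)))
  edges_from <- character(0)
  edges_to <- character(0)
  composite <- list()

  for (n in net$nodes) {
    r <- net$rules[[n]]
    k <- length(r$inputs)
    for (s in c(1L, 0L)) {
      for (p in prime_implicants(r$tt, k, value = s)) {
        lits <- implicant_literals(p, r$inputs)
        if (nrow(lits) == 0L) next     # constant rule: no structural input
        src <- vname(lits$input, lits$value)
        if (nrow(lits) == 1L) {
          edges_from <- c(edges_from, src)
          edges_to <- c(edges_to, vname(n, s))
        } else {
          cid <- paste0("{", paste(sort(src), collapse = ","), "}")
          composite[[cid]] <- sort(src)
          edges_from <- c(edges_from, src, cid)
          edges_to <- c(edges_to, rep(cid, length(src)), vname(n, s))
        }
      }
    }
  }

  vertices <- c(virtual, names(composite))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from, to = edges_to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = vertices)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  list(graph = g, virtual = virtual, composite = composite)
}
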