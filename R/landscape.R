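#' Epithelial/mesenchymal plane projection and landscape analysis
#'
#' Steady states are placed on the spectrum spanned by two reference
#' patterns (the unperturbed epithelial and mesenchymal steady states) using
#' the biorthogonal dual-pattern construction from associative-memory
#' theory. States are spin-encoded (OFF -> -1, ON -> +1); with reference
#' spins `xi^E`, `xi^M` and overlap matrix
#' `A[mu,nu] = mean(xi^mu * xi^nu)`, the raw overlaps of a state `sigma` are
#' `m[nu] = mean(xi^nu * sigma)` and the plane coordinates are
#' `a = solve(A, m)`. This is the unique linear scheme for which the
#' epithelial reference maps to `(a_M, a_E) = (0, 1)` and the mesenchymal
#' reference to `(1, 0)` exactly.
#'
#' @name state_landscape
NULL

spin <- function(state) 2 * as.numeric(state) - 1

#' Reference patterns for plane projection
#'
#' @param epithelial,mesenchymal Named 0/1 state vectors over the same nodes.
#' @return `reference_patterns` with spin vectors `xi_E`, `xi_M` and the 2x2
#'   overlap matrix `A`.
#' @export
reference_patterns <- function(epithelial, mesenchymal) {
  nodes <- names(epithelial)
  if (is.null(nodes) || !setequal(nodes, names(mesenchymal)))
    stop("reference states must be named over the same node set")
  xi_E <- spin(epithelial[nodes])
  xi_M <- spin(mesenchymal[nodes])
  A <- matrix(c(1, mean(xi_E * xi_M), mean(xi_E * xi_M), 1), 2, 2,
              dimnames = list(c("E", "M"), c("E", "M")))
  if (abs(A["E", "M"]) >= 1)
    stop("reference patterns must be distinct")
  structure(list(nodes = nodes, xi_E = xi_E, xi_M = xi_M, A = A),
            class = "reference_patterns")
}

#' Project a state onto the epithelial/mesenchymal plane
#'
#' @param refs A [reference_patterns()] object.
#' @param state Named 0/1 vector over the same node set (any order).
#' @param threshold Classification threshold on `a_E - a_M` (0.65):
#'   epithelial-like when `a_E - a_M > threshold`, mesenchymal-like when
#'   `a_M - a_E > threshold`, hybrid-like strictly in between; boundary
#'   values are assigned to the non-hybrid class.
#' @return List with `a_M`, `a_E`, raw overlaps `m`, and `label`.
#' @export
project_state <- function(refs, state, threshold = 0.65) {
  if (!setequal(names(state), refs$nodes))
    stop("state nodes do not match the reference node set")
  sigma <- spin(state[refs$nodes])
  m <- c(E = mean(refs$xi_E * sigma), M = mean(refs$xi_M * sigma))
  a <- solve(refs$A, m)
  d <- a[["E"]] - a[["M"]]
  # hybrid requires a strict inequality; boundary coordinates go to the
  # non-hybrid class (a small tolerance keeps rational boundaries exact)
  label <- if (d - threshold >= -1e-9) "epithelial-like"
           else if (-d - threshold >= -1e-9) "mesenchymal-like"
           else "hybrid-like"
  list(a_M = a[["M"]], a_E = a[["E"]], m = m, label = label)
}

#' Collect steady states across single-node perturbations
#'
#' Enumerates the attractors of the driven network and of every single-node
#' knockout and constitutive activation (perturbable nodes default to all
#' nodes except those already clamped), keeping steady states only and
#' labelling each row by its perturbation.
#'
#' @param net The driven `boolean_network` (e.g. TGFb clamped ON).
#' @param perturb_nodes Nodes to perturb (default: all unclamped nodes).
#' @param include_unperturbed Include the driven network itself.
#' @param max_exact,sim_runs Passed to [find_attractors()].
#' @return `steady_state_table`: `states` (0/1 matrix, one row per steady
#'   state), `perturbation` (labels), `n_complex` (complex attractors seen,
#'   excluded from the table), `approximate` flag.
#' @export
collect_steady_states <- function(net, perturb_nodes = NULL,
                                  include_unperturbed = TRUE,
                                  max_exact = 16L, sim_runs = 200L) {
  if (is.null(perturb_nodes)) perturb_nodes <- free_nodes(net)
  jobs <- list()
  if (include_unperturbed) jobs[["unperturbed"]] <- integer(0)
  for (n in perturb_nodes) {
    jobs[[paste0(n, "=0")]] <- stats::setNames(0L, n)
    jobs[[paste0(n, "=1")]] <- stats::setNames(1L, n)
  }
  rows <- list(); labs <- character(0); n_complex <- 0L; approx <- FALSE
  for (lab in names(jobs)) {
    pnet <- apply_perturbation(net, jobs[[lab]])
    atts <- find_attractors(pnet, max_exact = max_exact, sim_runs = sim_runs)
    for (a in atts) {
      if (a$approximate) approx <- TRUE
      if (a$kind == "steady_state") {
        rows[[length(rows) + 1L]] <- a$states[1, net$nodes]
        labs <- c(labs, lab)
      } else n_complex <- n_complex + 1L
    }
  }
  states <- do.call(rbind, rows)
  colnames(states) <- net$nodes
  structure(list(states = states, perturbation = labs,
                 n_complex = n_complex, approximate = approx),
            class = "steady_state_table")
}

#' @export
print.steady_state_table <- function(x, ...) {
  cat(sprintf("steady_state_table: %d steady states, %d perturbations%s\n",
              nrow(x$states), length(unique(x$perturbation)),
              if (x$n_complex) sprintf(", %d complex attractors excluded",
                                       x$n_complex) else ""))
  invisible(x)
}

#' Label every steady state in a table on the E/M spectrum
#'
#' @param table A [collect_steady_states()] table.
#' @param refs A [reference_patterns()] object.
#' @param threshold See [project_state()].
#' @return `data.frame` with `perturbation`, `a_M`, `a_E`, `label`.
#' @export
classify_landscape <- function(table, refs, threshold = 0.65) {
  res <- lapply(seq_len(nrow(table$states)), function(i)
    project_state(refs, table$states[i, ], threshold = threshold))
  data.frame(perturbation = table$perturbation,
             a_M = vapply(res, `[[`, numeric(1), "a_M"),
             a_E = vapply(res, `[[`, numeric(1), "a_E"),
             label = vapply(res, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}

#' Principal component analysis of a steady-state table
#'
#' States are spin-encoded (+/-1, `encoding = "spin"`) or kept 0/1, mean
#' centered and not scaled. Component signs are fixed deterministically: PC1
#' so that the mesenchymal reference scores negative, every other component
#' so that its largest-magnitude loading is positive.
#'
#' @param table A `steady_state_table`.
#' @param refs A [reference_patterns()] object (sign convention anchor).
#' @param encoding `"spin"` (+/-1, default) or `"binary"` (0/1).
#' @return List with `scores`, `loadings`, `sdev`.
#' @export
run_pca <- function(table, refs, encoding = c("spin", "binary")) {
  encoding <- match.arg(encoding)
  x <- table$states[, refs$nodes, drop = FALSE]
  if (encoding == "spin") x <- 2 * x - 1
  if (nrow(x) < 3L) stop("PCA requires at least 3 states")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L)))
    stop("degenerate table: all states identical")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  mes <- if (encoding == "spin") refs$xi_M else (refs$xi_M + 1) / 2
  mes_score <- drop((mes - p$center) %*% p$rotation)
  flip <- rep(1, ncol(p$rotation))
  if (mes_score[1] > 0) flip[1] <- -1
  for (j in seq_along(flip)[-1]) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) flip[j] <- -1
  }
  rot <- sweep(p$rotation, 2, flip, `*`)
  list(scores = sweep(p$x, 2, flip, `*`), loadings = rot, sdev = p$sdev)
}

#' Hierarchical clustering of a steady-state table
#'
#' Hamming distance (fraction of differing node states) with average linkage
#' by default; the flat cut returns `k` macro-clusters.
#'
#' @param table A `steady_state_table`.
#' @param k Number of flat clusters (3: epithelial/hybrid/mesenchymal).
#' @param method Linkage method for [stats::hclust()].
#' @return List with `tree` (hclust) and `clusters` (integer vector).
#' @export
run_hclust <- function(table, k = 3L, method = "average") {
  d <- stats::dist(table$states, method = "manhattan") / ncol(table$states)
  tree <- stats::hclust(d, method = method)
  list(tree = tree, clusters = stats::cutree(tree, k = k))
}
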