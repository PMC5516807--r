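#' End-to-end reproduction pipelines
#'
#' Orchestrate the screen and landscape stages from a single configuration
#' (an R list or a YAML file) with seeded, byte-reproducible TSV/JSON
#' reports.
#'
#' @name pipeline
NULL

#' Normalise a pipeline configuration
#'
#' @param config A named list or path to a YAML file. Recognised fields:
#'   `model` (rule-file path; default the packaged synthetic demo),
#'   `ref_states` (two-column TSV path), `input_node` (clamped ON driver;
#'   default `"TGFb"`), `readout` (default `"EMT"`), `excluded_nodes`,
#'   `orders` (default `1:2`), `n_runs` (default 1000), `max_rounds`
#'   (default 100), `seed` (required), `out_dir` (optional; reports written
#'   when set).
#' @return Validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    model = system.file("extdata", "emt_core_synthetic.bnet",
                        package = "boolmotifs"),
    ref_states = system.file("extdata", "emt_core_synthetic_states.tsv",
                             package = "boolmotifs"),
    input_node = "TGFb", readout = "EMT",
    excluded_nodes = NULL, orders = 1:2,
    n_runs = 1000L, max_rounds = 100L, seed = NULL, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("the pipeline configuration requires a seed")
  for (f in c("model", "ref_states"))
    if (!file.exists(cfg[[f]]))
      stop(sprintf("configured %s file '%s' does not exist", f, cfg[[f]]))
  cfg
}

pipeline_load <- function(cfg) {
  net <- read_boolean_network(cfg$model)
  states <- read_network_states(cfg$ref_states)
  if (is.null(cfg$excluded_nodes))
    cfg$excluded_nodes <- intersect(
      c(cfg$input_node, paste0(cfg$input_node, "R"), "Ecadherin",
        cfg$readout), net$nodes)
  driven <- apply_perturbation(net, stats::setNames(1L, cfg$input_node))
  list(cfg = cfg, net = net, driven = driven,
       epithelial = states[[1]], mesenchymal = states[[2]])
}

#' Run the combinatorial knockout screen pipeline
#'
#' Screens orders 1..K with the pool-exclusion rules (previous-order blockers
#' and their partners are removed from later pools), and emits the summary
#' table of pool size, combination count and blocker count per order,
#' alongside the blocker identities.
#'
#' @param config See [pipeline_config()].
#' @return List with `table` (data.frame: order, pool_size, n_combinations,
#'   n_blockers), `blockers` (per order), `results` (per order data.frames).
#' @export
run_screen_pipeline <- function(config = list()) {
  pl <- pipeline_load(pipeline_config(config))
  cfg <- pl$cfg
  sim <- sim_config(n_runs = cfg$n_runs, max_rounds = cfg$max_rounds,
                    seed = cfg$seed)
  init <- pl$epithelial
  single_blockers <- character(0)
  pair_blockers <- list()
  tab <- NULL; blockers <- list(); results <- list()
  for (ord in cfg$orders) {
    plan <- build_pool(pl$net, ord, excluded_nodes = cfg$excluded_nodes,
                       single_blockers = single_blockers,
                       pair_blockers = pair_blockers)
    if (plan$n_combinations > 0) {
      sr <- run_screen(pl$driven, plan, init, sim, readout = cfg$readout)
      res <- sr$results
      blk <- sr$blockers
    } else {
      res <- data.frame(); blk <- character(0)
    }
    tab <- rbind(tab, data.frame(order = ord, pool_size = length(plan$pool),
                                 n_combinations = plan$n_combinations,
                                 n_blockers = length(blk)))
    blockers[[as.character(ord)]] <- blk
    results[[as.character(ord)]] <- res
    if (ord == 1L) single_blockers <- blk
    if (ord == 2L) pair_blockers <- strsplit(blk, "+", fixed = TRUE)
  }
  out <- list(table = tab, blockers = blockers, results = results,
              seed = cfg$seed, model = cfg$model)
  if (!is.null(cfg$out_dir)) write_screen_report(out, cfg$out_dir)
  out
}

write_screen_report <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out$table, file.path(dir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ord in names(out$results))
    if (nrow(out$results[[ord]]))
      utils::write.table(out$results[[ord]],
                         file.path(dir, sprintf("screen_order%s.tsv", ord)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$blockers, file.path(dir, "blockers.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Run the steady-state landscape pipeline
#'
#' Collects the steady states of the driven network and of every single-node
#' perturbation, projects them on the epithelial/mesenchymal plane, labels
#' them, and computes PCA scores and hierarchical macro-clusters.
#'
#' @param config See [pipeline_config()].
#' @return List with `table` (steady_state_table), `landscape` (per-state
#'   data.frame with coordinates, labels, PC scores, cluster), `summary`
#'   (counts per label), `pca`, `hclust`.
#' @export
run_landscape_pipeline <- function(config = list()) {
  pl <- pipeline_load(pipeline_config(config))
  cfg <- pl$cfg
  set.seed(cfg$seed)
  refs <- reference_patterns(pl$epithelial, pl$mesenchymal)
  tab <- collect_steady_states(pl$driven)
  # include the unperturbed signal-free references in the table, as anchors
  tab$states <- rbind(tab$states,
                      pl$epithelial[pl$net$nodes],
                      pl$mesenchymal[pl$net$nodes])
  tab$perturbation <- c(tab$perturbation,
                        "reference_epithelial", "reference_mesenchymal")
  land <- classify_landscape(tab, refs)
  pca <- run_pca(tab, refs)
  hc <- run_hclust(tab, k = 3L)
  land$PC1 <- pca$scores[, 1]
  land$PC2 <- if (ncol(pca$scores) >= 2) pca$scores[, 2] else 0
  land$cluster <- hc$clusters
  out <- list(table = tab, landscape = land,
              summary = as.data.frame(table(label = land$label)),
              pca = pca, hclust = hc, seed = cfg$seed, model = cfg$model)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cbind(land, tab$states),
                       file.path(cfg$out_dir, "landscape.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
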