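#' The packaged synthetic EMT-like demonstration network
#'
#' A 10-node Boolean model authored for this package (not transcribed from
#' any published supplement) that reproduces the qualitative architecture of
#' TGFb-driven EMT: the TGFb signal activates a canonical (SMAD) and a
#' non-canonical (RAS/MEK) arm; both converge on the E-cadherin-repressing
#' transcription factors SNAI1 and ZEB; ZEB and miR200 mutually inhibit; the
#' EMT readout reports loss of E-cadherin. SNAI1 feeds back on RAS, so the
#' mesenchymal programme is self-sustaining once triggered. Both signal-free
#' reference phenotypes (epithelial, mesenchymal) are steady states.
#'
#' @return A `boolean_network` with 10 nodes.
#' @export
emt_example_network <- function() {
  read_boolean_network(system.file("extdata", "emt_core_synthetic.bnet",
                                   package = "boolmotifs", mustWork = TRUE))
}

#' Reference steady states of the demonstration network
#'
#' @return Named list with `epithelial` and `mesenchymal` 0/1 state vectors,
#'   both signal-free steady states of [emt_example_network()].
#' @export
emt_example_states <- function() {
  read_network_states(system.file("extdata", "emt_core_synthetic_states.tsv",
                                  package = "boolmotifs", mustWork = TRUE))
}

#' Default screen exclusions for the demonstration network
#'
#' The input signal, its receptor, the phenotype marker and the readout node
#' are never perturbed in a screen (they trivially force the readout).
#'
#' @return Character vector of node names.
#' @export
emt_example_exclusions <- function() {
  c("TGFb", "TGFbR", "Ecadherin", "EMT")
}
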