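# Small reference networks and canonical-form helpers shared across tests.

toggle_net <- function() parse_boolean_network(c("A, !B", "B, !A"))
mutual_net <- function() parse_boolean_network(c("A, B", "B, A"))
oscillator_net <- function() parse_boolean_network(c("A, B", "B, C", "C, !A"))
chain_net <- function() parse_boolean_network(c("A, 0", "B, A", "C, B"))

double_toggle_net <- function() {
  parse_boolean_network(c("A, !B", "B, !A", "C, !D", "D, !C"))
}

demo_driven <- function(net = emt_example_network()) {
  apply_perturbation(net, c(TGFb = 1L))
}

# canonical string form of a motif list / attractor list for set comparison
motif_keys <- function(motifs) {
  sort(vapply(motifs, function(m)
    paste(sprintf("%s=%d", names(m), m), collapse = ","), character(1),
    USE.NAMES = FALSE))
}

attractor_keys <- function(atts) {
  sort(vapply(atts, function(a)
    paste(a$kind,
          paste(sort(apply(a$states, 1, paste, collapse = "")),
                collapse = "|")), character(1), USE.NAMES = FALSE))
}

steady_state_keys <- function(atts) {
  st <- Filter(function(a) a$kind == "steady_state", atts)
  sort(vapply(st, function(a) paste(a$states[1, ], collapse = ""),
              character(1), USE.NAMES = FALSE))
}
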