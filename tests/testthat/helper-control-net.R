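# 12-node benchmark for exhaustive control verification: four independent
# mutual-activation switches plus one readout per switch.
grid_control_net <- function(pairs = 4) {
  lines <- character(0)
  for (i in seq_len(pairs)) {
    lines <- c(lines,
               sprintf("A%d, B%d", i, i),
               sprintf("B%d, A%d", i, i),
               sprintf("D%d, A%d | B%d", i, i, i))
  }
  parse_boolean_network(lines)
}
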