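# Small network builders shared across test files.

# connectome from explicit count matrices, all-excitatory unless stated
make_conn <- function(gap, syn, inhibitory = FALSE,
                      group = "inter") {
  n <- nrow(gap)
  roster <- data.frame(
    name = sprintf("T%02d", seq_len(n)),
    group = rep_len(group, n),
    inhibitory = rep_len(inhibitory, n)
  )
  connectome(gap, syn, roster, input = "counts")
}

# fully-connected directed synaptic layer on n neurons (count 1)
full_syn <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

# quick random network for property loops
prop_net <- function(seed, n = 8) {
  random_connectome(synth_spec(n = n, gap_density = 0.3, syn_density = 0.3,
                               inhibitory_fraction = 0.4, seed = seed))
}
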