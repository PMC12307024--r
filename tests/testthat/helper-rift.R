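# Shared fixtures, built in code.

# Six-electrode toy montage (cycle with one chord) for brute-force cluster
# oracles: A-B-C-D-E-F-A plus B-E.
toy_montage6 <- function() {
  rift_montage(LETTERS[1:6],
               rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                     c("D", "E"), c("E", "F"), c("F", "A"), c("B", "E")))
}

# Small, cheap simulation configuration for unit tests.
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 2, n_trials_per_condition = 4, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Fully deterministic (noise- and jitter-free) configuration.
noiseless_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 1, n_trials_per_condition = 1,
                   noise_sd = 0, alpha_amp = 0,
                   participant_jitter_sdlog = 0, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a rift_epochs directly from a data array (tests of analysis ops on
# hand-constructed signals).
make_epochs <- function(data, sample_rate = 1000, montage = default_montage(),
                        condition = NULL, t0 = -dim(data)[3] / (2 * sample_rate)) {
  n_trials <- dim(data)[1]
  if (is.null(condition)) {
    condition <- rep(c("related", "unrelated"), length.out = n_trials)
  }
  time <- t0 + (seq_len(dim(data)[3]) - 1) / sample_rate
  rifteeg:::new_epoch_set(data, time, condition, "P01", sample_rate, montage)
}

# Build a rift_pc percent-change map directly from a 4-D array
# (participant x condition x channel x frequency).
make_pc <- function(arr, freqs, montage) {
  dimnames(arr) <- list(sprintf("P%02d", seq_len(dim(arr)[1])),
                        c("related", "unrelated"), montage$channels, freqs)
  structure(list(pc = arr, freqs = freqs, montage = montage),
            class = "rift_pc")
}

# Independent connected-components oracle built on igraph.
igraph_components <- function(montage, nodes) {
  g <- igraph::graph_from_adjacency_matrix(montage$adjacency, mode = "undirected")
  sub <- igraph::induced_subgraph(g, nodes)
  comp <- igraph::components(sub)
  split(igraph::V(sub)$name, comp$membership)
}
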