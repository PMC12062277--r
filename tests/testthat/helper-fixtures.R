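# Shared fixtures, all generated in code.

tiny_cohort <- function(seed = 3L, n_complete = 40L, n1 = 10L, n2 = 5L,
                        d = c(30L, 25L), n_informative = 5L, effect = 2) {
  cfg <- simulation_config(
    n_samples_complete = n_complete, n_samples_mod1_only = n1,
    n_samples_mod2_only = n2, n_nodes_per_modality = d,
    n_informative = n_informative, effect_size = effect, seed = seed
  )
  generate_cohort(cfg)
}

# dense symmetric-normalized adjacency oracle (with unit self-loops)
dense_norm_adjacency <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph)) + diag(igraph::vcount(graph))
  dm <- 1 / sqrt(rowSums(A))
  A * outer(dm, dm)
}

# a small trained unimodal model shared by attribution tests (built once)
small_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- tiny_cohort(seed = 21L, n_complete = 60L, n1 = 0L, n2 = 0L,
                        d = c(20L, 20L), n_informative = 4L, effect = 2)
      mdl <- train_multiomics(co, modalities = "transcriptomics",
                              encoder_cfg = encoder_config(channels = 2L,
                                                           embedding_dim = 8L),
                              epochs = 8L, batch_size = 16L, lr = 3e-3,
                              seed = 5L)
      cache <<- list(cohort = co, model = mdl)
    }
    cache
  }
})
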