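# Shared small fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.acceptance_cache <- new.env()

tiny_config <- function(...) {
  base <- list(n_layers = 2L, gcn_dim = 8L, attn_heads = c(2L, 1L),
               attn_dim = 4L, graph_dim = 6L, q_dim = 5L, cell_dim = 20L,
               fp_bits = 32L, conv_filters = 3L, kernel_size = 4L,
               cell_stride = 2L, fp_stride = 4L, branch_dim = 7L,
               fuse_dim = 6L, ha_dim = 5L, hidden_dim = 9L, dropout = 0)
  do.call(gf_config, utils::modifyList(base, list(...)))
}

.fixture_env <- new.env()

tiny_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- simulate_drug_response(
      n_drugs = 5L, n_cells = 4L, cell_dim = 20L, noise_sd = 0.05,
      seed = 99L
    )
  }
  .fixture_env$ds
}

tiny_featurized <- function() {
  if (is.null(.fixture_env$feats)) {
    .fixture_env$feats <- featurize_drugs(tiny_dataset()$drugs, n_bits = 32L)
  }
  .fixture_env$feats
}

tiny_model_data <- function(cfg = tiny_config()) {
  ds <- tiny_dataset()
  gf_model_data(tiny_featurized(), ds$cells, ds$responses, cfg)
}
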