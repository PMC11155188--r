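## Shared fixtures: a deliberately small network and dataset so the
## module-level training tests stay fast. Sizes here are test conveniences,
## not study conditions.

small_net <- function(image_size = 32) {
  hybrid_config(image_depth = 8, base_width = 4, image_size = image_size,
                gin_blocks = 2, graph_hidden = 8, fusion_hidden = 16,
                dropout_rate = 0)
}

small_graph_cfg <- function() graph_config(target_segments = 30, k = 4)

## one small prepared center of separable phantoms
small_prepared <- function(n_benign = 8, n_malignant = 8, seed = 11,
                           copies = 2) {
  smp <- generate_center(phantom_config(
    n_benign = n_benign, n_malignant = n_malignant, center_id = "t",
    speckle_sigma = 0.05, contrast = 0.5, seed = seed))
  prepare_center(smp, side = 32, graph_cfg = small_graph_cfg(),
                 augment = augment_params(copies = copies), seed = seed)
}

## random parameter list shaped like a tiny model, for aggregation tests
random_param_list <- function(n_blocks = 10, seed = 1) {
  set.seed(seed)
  p <- list()
  for (i in seq_len(n_blocks)) {
    p[[sprintf("block%02d", i)]] <- if (i %% 2 == 0) {
      matrix(stats::rnorm(12), 3, 4)
    } else {
      stats::rnorm(5)
    }
  }
  p
}
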